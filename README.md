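# syllableseq

Unsupervised discovery of behavioral syllables and grammar from overhead
depth video of a freely behaving rodent.

Spontaneous rodent behavior is organized at the sub-second timescale into
brief, reused motifs of 3D pose dynamics — *behavioral syllables* — strung
together by predictable transition statistics, a behavioral *grammar*.
syllableseq implements the full path from raw depth video to that
description, for behavioral neuroscientists who want an ethogram that is
learned from the data rather than imposed by a human labeler:

1. **Measurement** — background estimation, animal segmentation,
   egocentric (heading-normalized) alignment, and spine height profiles
   from depth frames in millimetres.
2. **Compression** — PCA or random projection of the aligned frames into a
   low-dimensional pose series \(x_t \in \mathbb{R}^D\).
3. **Model** — a sticky HDP-AR-HMM: per-syllable linear autoregressions
   \(x_t = \sum_l A_{k,l} x_{t-l} + b_k + \epsilon_t\),
   \(\epsilon_t \sim N(0, \Sigma_k)\), switching under a weak-limit sticky
   hierarchical-Dirichlet-process prior
   \(\pi_j \sim \mathrm{Dir}(\alpha\beta + \kappa e_j)\), fit by Gibbs
   sampling (forward-filter/backward-sample label draws,
   matrix-normal/inverse-Wishart emission updates, auxiliary-table HDP
   updates). Every frame receives exactly one syllable label; the number
   of used syllables adapts to the data.
4. **Analytics** — syllable usages and durations, run-encoded transition
   matrices, state-map graphs, signed difference maps between conditions,
   and per-syllable permutation tests with Benjamini–Hochberg FDR control.
5. **Validation** — ground-truth synthetic generators (switching AR, and
   a module-free control), held-out log-likelihood comparison against a
   continuous single-AR baseline and a Gaussian-mixture-over-frames
   baseline, and a syllable-count-versus-data-volume curve.

## A worked example

```r
library(syllableseq)

# ground-truth-known synthetic pose dynamics: 5 syllables, ~300 ms dwell
g <- generate_arhmm_series(n_states = 5, dim = 10, ar_lag = 1,
                           mean_duration_frames = 9, n_frames = 6000,
                           noise_scale = 0.1, seed = 17)

cfg <- fit_config(n_sweeps = 50, n_burnin = 25, seed = 2,
                  K_max = 20, ar_lag = 1, gamma = 1, alpha = 1,
                  target_mean_duration_s = 0.3)
fit <- fit_arhmm(g$series, cfg)
glance(fit)
#> # A tibble: 1 x 8
#>   n_frames n_used_states K_max ar_lag kappa joint_logprob mean_duration_s n_sweeps
#>      <int>         <int> <int>  <int> <dbl>         <dbl>           <dbl>    <int>
#> 1     6000             5    20      1     8        31732.           0.328       50

tidy(fit)
#> # A tibble: 5 x 5
#>   syllable usage n_instances mean_duration_s noise_sd
#>      <int> <dbl>       <int>           <dbl>    <dbl>
#> 1        1 0.213         121           0.352    0.245
#> 2        2 0.211         124           0.341    0.240
#> 3        3 0.198         119           0.332    0.276
#> 4        4 0.197         126           0.313    0.221
#> 5        5 0.181         120           0.302    0.223

u <- usages(fit$labels)              # frame-based syllable usage, sums to 1
P <- transition_matrix(fit$labels)   # run-encoded, row-stochastic
map <- build_state_map(u, P, min_usage = 0.01, min_edge_p = 0.05)
autoplot(map)                        # nodes sized by usage, edges by p
write_state_map(map, "state_map.graphml")
```

The five used states at ~0.3 s mean duration recover the five generating
regimes; after matching discovered to true states, frame-label agreement
with the ground truth is 100% in this run. On a module-free control series
(`generate_nonmodular_series()`) the same sampler collapses onto a single
state covering >90% of frames — the model does not invent modules.

A YAML-driven command line covers the same stages
(`simulate`, `extract`, `features`, `train`, `apply`, `analyze`,
`compare`, `evaluate`):

```sh
Rscript inst/scripts/syllableseq train --config config.yaml --seed 3
```

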