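---
title: "Discovering behavioral syllables with syllableseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering behavioral syllables with syllableseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syllableseq)
```

## The model

syllableseq treats the spontaneous behavior of a freely moving rodent as a
sequence of brief, reused motifs of 3D pose dynamics — behavioral
*syllables* — strung together by a probabilistic *grammar*. The observation
at frame $t$ is a low-dimensional pose vector $x_t \in \mathbb{R}^D$
obtained by compressing egocentrically aligned depth frames. Conditional on
a discrete syllable label $z_t = k$, the pose evolves as a linear
autoregression with Gaussian noise:

$$x_t = \sum_{l=1}^{r} A_{k,l}\, x_{t-l} + b_k + \epsilon_t,
  \qquad \epsilon_t \sim \mathcal N(0, \Sigma_k),$$

and the labels follow a Markov chain, $z_t \mid z_{t-1} = j \sim \pi_j$,
whose rows are drawn from a weak-limit truncation of a sticky hierarchical
Dirichlet process:

$$\beta \sim \mathrm{Dir}(\gamma / K, \ldots, \gamma / K), \qquad
  \pi_j \sim \mathrm{Dir}(\alpha \beta + \kappa\, e_j).$$

The hierarchical prior shares a global list of candidate syllables
(weights $\beta$) across all transition rows, which is what lets the number
of *occupied* states adapt to the data rather than being fixed in advance;
the sticky mass $\kappa$ on the diagonal biases self-transitions and sets
the timescale at which the model looks for structure. Every frame carries
exactly one label: the first $r$ frames, which have no modeled likelihood,
inherit the label of the first modeled frame.

Fitting is by Gibbs sampling. Each sweep draws, from their exact
conditionals:

1. the label sequence, by forward filtering and backward sampling on
   log-space messages normalized per frame (underflow-proof at any length);
2. each state's $(A_k, b_k, \Sigma_k)$, from the conjugate
   matrix-normal/inverse-Wishart posterior given its assigned frames
   (unused states resample from the prior);
3. the transition rows and global weights, via the standard
   auxiliary-table counts with the sticky correction that discounts
   self-transition tables spawned by $\kappa$.

The returned point estimate is the final post-burn-in sample, with states
relabeled in descending usage order. State identity across independent runs
is resolved by usage rank only; no cross-run matching is attempted.

## Parameters that matter

* `target_mean_duration_s` (default 0.3 s): the timescale knob. It is
  converted to the sticky mass by $\kappa = \alpha (d - 1)$, where
  $d$ is the target dwell in frames, so that the prior-mean
  self-transition probability $\kappa / (\alpha + \kappa)$ yields a
  geometric dwell with mean $d$. At the default 30 frames per second,
  0.3 s gives $d = 9$ frames. The prior is deliberately loose: syllables
  from roughly a hundred milliseconds to over a second remain reachable.
* `K_max` (default 100): the weak-limit truncation. It is an upper bound,
  not a target; the HDP concentrates mass on far fewer states. Reducing it
  (40 in the validation harness) speeds up fitting with no effect once the
  occupied count is well below the bound.
* `gamma`, `alpha` (defaults 10, 5): top-level and per-row concentrations.
  Larger values admit more states and smoother rows. The validation
  harness uses `gamma = alpha = 1`, which prunes redundant states more
  aggressively; this matters for the module-free control below, where the
  posterior should collapse onto a single regime.
* `ar_lag` (default 3): the AR order $r$. Higher lags give richer
  within-syllable dynamics but make the frames around a syllable switch
  (whose lags straddle the boundary) harder to attribute; with the short
  dwells used in the recovery harness a lag of 1 is used there.
* Emission prior: matrix-normal with identity column scale, and
  inverse-Wishart with $D + 2$ degrees of freedom and scale $s_0 I$,
  where $s_0$ is the mean per-dimension variance of the series — the
  identity-scale prior expressed on data standardized by their global
  variance. This is weakly informative and keeps unused states' draws on
  the data's scale.

## The synthetic generator

`generate_arhmm_series()` *is* the study condition for validation: it
draws per-state dynamics as rotation-plus-contraction lag matrices
(rescaled so the companion matrix's spectral radius is at most 0.99, which
guarantees stable, finite trajectories), spreads the states' fixed points
in pose space (`separation`, default 4, against emission noise 0.1), and
samples labels from a sticky chain with geometric dwell. The defaults
mirror what the method expects of real data: five to twenty reusable
regimes, dwell about 9 frames at 30 fps (about 300 ms), and
block-structured switching. `generate_nonmodular_series()` produces the
opposite: one slowly varying stable AR(1) regime with no change points,
used to check that the model does not invent modules.

`render_depth_video()` draws the measurement side: a half-ellipsoid animal
on a flat floor, seen from above in millimetre depth units, with the
posterior half slightly lowered so the 180° heading ambiguity is
resolvable from shape. It does not emulate limbs, tail, fur, occlusions,
multi-animal scenes, or structured sensor artifacts — so passing the
extraction tests shows geometric correctness of the pipeline, not
robustness to everything a real depth camera does.

Validation on these synthetics demonstrates internal correctness
(the sampler targets the right posterior, parameters are recoverable,
controls behave); it cannot certify performance on real recordings, where
pose dimensionality, noise and non-stationarity are richer.

## Numerical choices

* Forward messages are kept in log space and renormalized every frame;
  a non-finite message aborts with the frame index rather than
  propagating NaN.
* Posterior scatter matrices are symmetrized and lightly jittered
  (relative $10^{-9}$) before Cholesky, guarding against round-off
  indefiniteness; a genuinely non-positive-definite covariance is a hard
  error.
* Degenerate orientation (a circularly symmetric mask) falls back to
  heading 0 before disambiguation; ties in the anterior rule keep the
  moment axis.
* Transition counting for grammar analytics is run-length based, so
  self-transitions are structurally absent from state maps; the sticky
  model's dwell handling would otherwise dominate every edge. Frame-based
  usage is the default (`usage_mode = "frames"`).
* Benjamini–Hochberg is the multiple-testing procedure behind the
  per-syllable condition comparison, applied to two-sided permutation
  p-values computed by shuffling *session* condition assignments —
  sessions, not frames, are the exchangeable replicates.

## Problem sizes in the validation harness

The test-suite and acceptance-script fits are sized for a single CPU:
recovery uses 5 states in 10 dimensions over 20,000 frames with 75 Gibbs
sweeps at `K_max = 40`; the module-free control 8,000 frames with a
200-sweep chain (merging redundant near-identical states is the slowest
Gibbs move, so the collapse onto one regime needs the longest run); the
model-comparison harness ten independent 4,000-frame replicates; the
data-volume curve 16,000 frames over fractions 1/8 to 1. These are the
package's chosen validation conditions and are recorded in each output's
metadata.

## Design choices where the design was open

* Sticky HDP-HMM in the weak limit rather than an explicit-duration
  semi-Markov model: both describe the intended switching behavior, and
  the weak-limit Gibbs sampler is simpler, standard, and exactly testable
  against enumeration.
* The depth-video interchange format is a directory of 16-bit TIFF frames
  with a YAML sidecar, lossless at 1 mm quantization; models serialize to
  JSON at full floating-point precision, labels and summaries to CSV with
  `# key: value` metadata comments, graphs to GraphML/DOT.
* The command-line pipeline (`run_stage()`, `inst/scripts/syllableseq`)
  validates configuration keys strictly — unknown keys are errors — and
  writes outputs atomically with the full configuration echoed, so a run
  is reproducible from any one of its output files.

## Known limitations

* Syllables are linear-Gaussian regimes; strongly nonlinear
  within-syllable dynamics are approximated by switching more often.
* A single timescale is modeled; faster rhythms (whisking, breathing) and
  slower states (arousal) are outside the prior's reach.
* No size normalization across animals, no multi-animal scenes, no limb
  or whisker kinematics.
* The extraction stage is a standard moments-based aligner; any published
  extraction algorithm for a specific camera should supersede it for real
  data.
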