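test_that("one-component mixture equals the closed-form Gaussian MLE score", {
  set.seed(41)
  Ytr <- matrix(rnorm(600), 200, 3)
  Yte <- matrix(rnorm(150), 50, 3)
  g <- gmm_baseline(pose_series(Ytr, 30), pose_series(Yte, 30),
                    n_components = 1, seed = 1)
  mu <- colMeans(Ytr)
  S <- crossprod(sweep(Ytr, 2, mu)) / nrow(Ytr)
  oracle <- sum(vapply(seq_len(nrow(Yte)), function(i)
    dense_mvn_logpdf(Yte[i, ], mu, S), numeric(1)))
  expect_equal(g$total_loglik, oracle, tolerance = 1e-6)
})

test_that("overfitting a mixture to i.i.d. Gaussian frames buys nothing held out", {
  set.seed(42)
  Ytr <- matrix(rnorm(2000), 500, 4)
  Yte <- matrix(rnorm(800), 200, 4)
  g1 <- gmm_baseline(Ytr, Yte, 1, seed = 1)
  g5 <- gmm_baseline(Ytr, Yte, 5, seed = 1)
  expect_lt(abs(g1$per_frame - g5$per_frame), 0.25)
  # seeded determinism
  expect_identical(gmm_baseline(Ytr, Yte, 3, seed = 2)$total_loglik,
                   gmm_baseline(Ytr, Yte, 3, seed = 2)$total_loglik)
})

test_that("duplicate models in a comparison score identically", {
  g <- generate_arhmm_series(2, 3, 1, 8, 1200, 0.2, seed = 43)
  Y <- g$series$values
  train <- pose_series(Y[1:900, ], 30)
  test <- pose_series(Y[901:1200, ], 30)
  base <- ar_baseline(train, ar_lag = 1)
  rep <- heldout_compare(train, test, list(a = base, b = base))
  expect_equal(rep$total_loglik[1], rep$total_loglik[2])
  expect_equal(rep$per_frame_loglik, rep$total_loglik / 300)
  expect_true(all(is.finite(rep$total_loglik)))
})

test_that("models fit on different data are rejected by checksum", {
  g <- generate_arhmm_series(2, 3, 1, 8, 1200, 0.2, seed = 44)
  Y <- g$series$values
  train <- pose_series(Y[1:900, ], 30)
  other <- pose_series(Y[101:1000, ], 30)
  test <- pose_series(Y[901:1200, ], 30)
  base <- ar_baseline(other, ar_lag = 1)
  expect_error(heldout_compare(train, test, list(m = base)),
               "checksum")
})

test_that("the switching model out-predicts both baselines on switching data", {
  g <- generate_arhmm_series(4, 6, 1, 10, 4000, noise_scale = 0.15,
                             seed = 45)
  Y <- g$series$values
  train <- pose_series(Y[1:3000, ], 30)
  test <- pose_series(Y[3001:4000, ], 30)
  cfg <- fit_config(n_sweeps = 40, n_burnin = 20, seed = 3, K_max = 20,
                    ar_lag = 1, gamma = 1, alpha = 1,
                    target_mean_duration_s = 10 / 30)
  fit <- fit_arhmm(train, cfg)
  rep <- heldout_compare(train, test, list(
    arhmm = fit,
    ar_continuous = ar_baseline(train, ar_lag = 1),
    gmm = gmm_baseline(train, test, 8, seed = 3)))
  scores <- setNames(rep$per_frame_loglik, rep$model)
  expect_gt(scores[["arhmm"]], scores[["ar_continuous"]])
  expect_gt(scores[["arhmm"]], scores[["gmm"]])
})

test_that("the control analysis is internally consistent on identical inputs", {
  g <- generate_arhmm_series(2, 3, 1, 8, 1500, 0.2, seed = 46)
  cfg <- fit_config(n_sweeps = 15, n_burnin = 5, seed = 2, K_max = 8,
                    ar_lag = 1, gamma = 1, alpha = 1)
  out <- cross_likelihood_control(g$series, g$series, cfg,
                                  min_effective_states = 1)
  expect_equal(out$modular$n_effective_states,
               out$nonmodular$n_effective_states)
  expect_equal(out$modular$largest_state_share,
               out$nonmodular$largest_state_share)
})

test_that("a single-fraction curve equals a direct fit's state count", {
  g <- generate_arhmm_series(3, 4, 1, 8, 1500, 0.15, seed = 47)
  cfg <- fit_config(n_sweeps = 15, n_burnin = 5, seed = 4, K_max = 10,
                    ar_lag = 1, gamma = 1, alpha = 1)
  curve <- state_count_curve(g$series, 1, cfg)
  direct <- fit_arhmm(g$series, cfg)
  u <- usages(direct$labels)
  expect_equal(curve$used_states, sum(u$usage >= 0.01))
  expect_equal(curve$n_frames, 1500)
})

test_that("too-short prefixes are skipped with a message", {
  g <- generate_arhmm_series(2, 2, 1, 6, 600, 0.2, seed = 48)
  cfg <- fit_config(n_sweeps = 8, n_burnin = 4, seed = 1, K_max = 6,
                    ar_lag = 3)
  expect_message(
    curve <- state_count_curve(g$series, c(0.01, 1), cfg),
    "skipped")
  expect_equal(nrow(curve), 1)
  expect_equal(attr(curve, "skipped"), 0.01)
})
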