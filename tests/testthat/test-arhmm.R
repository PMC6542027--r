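test_that("ar_loglik matches hand-computed unit-Gaussian values", {
  m <- arhmm_model(A = list(diag(1)), b = matrix(0, 1, 1),
                   Sigma = array(1, c(1, 1, 1)),
                   pi = matrix(1, 1, 1), beta = 1, ar_lag = 1)
  # at the mean: -log(sqrt(2*pi))
  expect_equal(ar_loglik(m, 1, matrix(c(0.7, 0.7), 2, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # unit residual
  expect_equal(ar_loglik(m, 1, matrix(c(0, 1), 2, 1)),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
})

test_that("ar_loglik equals a dense multivariate-normal evaluation", {
  set.seed(10)
  D <- 3; r <- 2
  A <- matrix(rnorm(D * D * r, sd = 0.3), D)
  b <- rnorm(D)
  S <- crossprod(matrix(rnorm(D * D), D)) + diag(D)
  m <- arhmm_model(A = list(A), b = matrix(b, D, 1),
                   Sigma = array(S, c(D, D, 1)),
                   pi = matrix(1, 1, 1), beta = 1, ar_lag = r)
  for (i in 1:5) {
    w <- matrix(rnorm((r + 1) * D), r + 1, D)
    lags <- as.numeric(t(w[r:1, ]))   # x_{t-1} first
    mu <- as.numeric(A %*% lags) + b
    expect_equal(ar_loglik(m, 1, w), dense_mvn_logpdf(w[r + 1, ], mu, S),
                 tolerance = 1e-9)
  }
})

test_that("non-positive-definite noise fails loudly", {
  expect_error(
    arhmm_model(A = list(diag(1)), b = matrix(0, 1, 1),
                Sigma = array(-1, c(1, 1, 1)),
                pi = matrix(1, 1, 1), beta = 1, ar_lag = 1),
    "positive definite")
})

test_that("a degenerate transition matrix labels every frame with the one live state", {
  m <- arhmm_model(
    A = list(matrix(0.5, 1, 1), matrix(0.5, 1, 1)),
    b = matrix(c(0, 5), 1, 2), Sigma = array(c(1, 1), c(1, 1, 2)),
    pi = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE), beta = c(1, 0),
    ar_lag = 1)
  z <- resample_labels(m, pose_series(matrix(rnorm(50), 50, 1), 30),
                       seed = 1)
  expect_true(all(z$labels == 1))
  expect_length(z$labels, 50)
})

test_that("label draws match exhaustive posterior enumeration (TV < 0.02)", {
  m <- tiny_two_state_model()
  Y <- matrix(c(0.1, 0.5, -0.3, 0.4), 4, 1)
  series <- pose_series(Y, fps = 30)
  enum <- as.matrix(expand.grid(z1 = 1:2, z2 = 1:2, z3 = 1:2))
  lp <- apply(enum, 1, function(z) {
    ll <- sum(vapply(1:3, function(t)
      ar_loglik(m, z[t], Y[t:(t + 1), , drop = FALSE]), numeric(1)))
    ll + log(m$beta[z[1]]) + log(m$pi[z[1], z[2]]) + log(m$pi[z[2], z[3]])
  })
  post <- exp(lp - max(lp)); post <- post / sum(post)
  n <- 20000
  set.seed(42)
  draws <- replicate(n, paste(resample_labels(m, series)$labels[2:4],
                              collapse = ""))
  emp <- table(factor(draws, levels = apply(enum, 1, paste, collapse = ""))) / n
  expect_lt(0.5 * sum(abs(as.numeric(emp) - post)), 0.02)
})

test_that("labels from well-separated two-state data recover the truth", {
  g <- generate_arhmm_series(2, 3, 1, 12, 3000, noise_scale = 0.05,
                             seed = 14)
  z <- resample_labels(g$truth$true_params, g$series, seed = 3)
  expect_gte(match_accuracy(g$truth$true_labels, z$labels), 0.95)
})

test_that("emission posterior concentrates on the generating line dynamics", {
  # noiseless-ish line x_t = x_{t-1} + v
  v <- 0.05
  T_ <- 2000
  set.seed(8)
  Y <- matrix(cumsum(c(0, rep(v, T_ - 1))) + rnorm(T_, sd = 1e-4), T_, 1)
  vague <- list(M0 = matrix(0, 1, 2), K0 = diag(1e-8, 2),
                S0 = diag(1e-8, 1), nu0 = 3)
  draws <- replicate(50, {
    em <- resample_emissions(Y, rep(1L, T_), K_max = 1, ar_lag = 1,
                             prior = vague)
    c(em$A[[1]][1, 1], em$b[1, 1])
  })
  # OLS oracle on the same frames
  X <- cbind(Y[-T_, 1], 1)
  ols <- solve(crossprod(X), crossprod(X, Y[-1, 1]))
  expect_lt(abs(mean(draws[1, ]) - ols[1]), 1e-3)
  expect_lt(abs(mean(draws[2, ]) - ols[2]), 1e-3)
})

test_that("states with no assigned frames draw from the prior", {
  set.seed(9)
  Y <- matrix(rnorm(400), 200, 2)
  draws <- replicate(200, {
    em <- resample_emissions(Y, rep(1L, 200), K_max = 2, ar_lag = 1)
    em$b[, 2]
  })
  # prior mean of B is 0; column scale identity -> b prior mean 0 with
  # spread governed by the inverse-Wishart noise scale
  expect_lt(max(abs(rowMeans(draws))), 0.5)
  expect_gt(sd(draws[1, ]), 0.2)
})

test_that("duplicating the data shrinks the emission posterior", {
  set.seed(11)
  g <- generate_arhmm_series(1, 2, 1, 10, 300, 0.3, seed = 11)
  Y <- g$series$values
  spread <- function(Ymat) {
    d <- replicate(60, {
      em <- resample_emissions(Ymat, rep(1L, nrow(Ymat)), 1, 1)
      em$A[[1]][1, 1]
    })
    var(d)
  }
  expect_lt(spread(rbind(Y, Y)), spread(Y))
})

test_that("huge kappa forces self-transitions toward 1", {
  hdp <- list(gamma = 2, alpha = 1, kappa = 1e6, beta = rep(1 / 3, 3))
  set.seed(2)
  draws <- replicate(50, {
    tr <- resample_transitions(c(1L, 1L), hdp, 3)
    diag(tr$pi)
  })
  expect_true(all(rowMeans(draws) > 0.99))
})

test_that("transition posterior mean matches the analytic Dirichlet mean", {
  # kappa = 0, uniform alpha*beta, counts from labels 1,1,2,2:
  # n_1. = (1, 1), n_2. = (0, 1)
  hdp <- list(gamma = 1e8, alpha = 2, kappa = 0, beta = c(0.5, 0.5))
  # gamma huge -> beta stays essentially uniform across draws
  set.seed(3)
  draws <- replicate(4000, resample_transitions(c(1L, 1L, 2L, 2L), hdp, 2)$pi)
  post_mean <- apply(draws, c(1, 2), mean)
  analytic <- rbind(c(2, 2) / 4, c(1, 2) / 3)
  expect_lt(max(abs(post_mean - analytic)), 0.02)
})

test_that("rows of unused states equal the prior mean", {
  hdp <- list(gamma = 1e8, alpha = 5, kappa = 0, beta = rep(0.25, 4))
  set.seed(4)
  draws <- replicate(3000, resample_transitions(rep(1L, 10), hdp, 4)$pi[3, ])
  expect_lt(max(abs(rowMeans(draws) - 0.25)), 0.03)
})

test_that("kappa closed form and its simulated dwell agree", {
  expect_equal(mean_duration_to_kappa(0.3, 30, 1), 8)
  expect_equal(mean_duration_to_kappa(2 / 30, 30, 5), 5)
  expect_error(mean_duration_to_kappa(1 / 60, 30, 1), "one frame")
  # dwell under the prior-mean self-transition probability
  alpha <- 1; fps <- 30; target <- 0.3
  kappa <- mean_duration_to_kappa(target, fps, alpha)
  p_self <- kappa / (alpha + kappa)
  set.seed(5)
  dwells <- rgeom(20000, 1 - p_self) + 1
  expect_lt(abs(mean(dwells) / fps - target) / target, 0.1)
})

test_that("the full fit recovers a well-separated five-state model", {
  g <- generate_arhmm_series(5, 6, 1, 9, 6000, noise_scale = 0.1, seed = 17)
  cfg <- fit_config(n_sweeps = 50, n_burnin = 25, seed = 2, K_max = 20,
                    ar_lag = 1, gamma = 1, alpha = 1)
  fit <- fit_arhmm(g$series, cfg)
  expect_gte(match_accuracy(g$truth$true_labels, fit$labels$labels), 0.9)
  used <- length(unique(fit$labels$labels))
  expect_gte(used, 3); expect_lte(used, 7)
  # every frame labeled; state 1 is the most used
  expect_length(fit$labels$labels, 6000)
  u <- usages(fit$labels)
  expect_equal(u$syllable[which.max(u$usage)], 1L)
  # diagnostics finite throughout
  expect_true(all(is.finite(fit$diagnostics$joint_logprob)))
})

test_that("fits are reproducible under a fixed seed", {
  g <- generate_arhmm_series(2, 3, 1, 8, 800, 0.2, seed = 19)
  cfg <- fit_config(n_sweeps = 10, n_burnin = 5, seed = 7, K_max = 10,
                    ar_lag = 1)
  f1 <- fit_arhmm(g$series, cfg)
  f2 <- fit_arhmm(g$series, cfg)
  expect_identical(f1$labels$labels, f2$labels$labels)
  expect_identical(f1$model$pi, f2$model$pi)
})

test_that("held-out loglik of a one-state model is the sum of per-frame AR logliks", {
  m <- arhmm_model(A = list(matrix(0.6, 1, 1)), b = matrix(0.1, 1, 1),
                   Sigma = array(0.4, c(1, 1, 1)),
                   pi = matrix(1, 1, 1), beta = 1, ar_lag = 1)
  Y <- matrix(rnorm(30), 30, 1)
  per_frame <- sum(vapply(2:30, function(t)
    ar_loglik(m, 1, Y[(t - 1):t, , drop = FALSE]), numeric(1)))
  expect_equal(heldout_loglik(m, pose_series(Y, 30)), per_frame,
               tolerance = 1e-10)
})

test_that("held-out loglik matches brute-force enumeration on a tiny instance", {
  m <- tiny_two_state_model()
  Y <- matrix(c(0.1, 0.5, -0.3, 0.4, 0.2), 5, 1)
  enum <- as.matrix(expand.grid(rep(list(1:2), 4)))
  lp <- apply(enum, 1, function(z) {
    ll <- sum(vapply(1:4, function(t)
      ar_loglik(m, z[t], Y[t:(t + 1), , drop = FALSE]), numeric(1)))
    ll + log(m$beta[z[1]]) + sum(log(m$pi[cbind(z[-4], z[-1])]))
  })
  brute <- max(lp) + log(sum(exp(lp - max(lp))))
  expect_equal(heldout_loglik(m, pose_series(Y, 30)), brute,
               tolerance = 1e-8)
})

test_that("held-out loglik is additive over independent forward passes", {
  m <- tiny_two_state_model()
  Y <- matrix(rnorm(40), 40, 1)
  one <- heldout_loglik(m, pose_series(Y, 30))
  expect_equal(2 * one,
               heldout_loglik(m, pose_series(Y, 30)) +
                 heldout_loglik(m, pose_series(Y, 30)),
               tolerance = 1e-12)
})

test_that("labels sampled with a forced initial distribution respect pi rows summing to one", {
  g <- generate_arhmm_series(3, 2, 1, 6, 400, 0.2, seed = 23)
  cfg <- fit_config(n_sweeps = 5, n_burnin = 2, seed = 1, K_max = 8,
                    ar_lag = 1)
  fit <- fit_arhmm(g$series, cfg)
  expect_true(all(abs(rowSums(fit$model$pi) - 1) < 1e-10))
  expect_lt(abs(sum(fit$model$beta) - 1), 1e-10)
  for (k in seq_len(fit$model$K_max))
    expect_silent(chol(matrix(fit$model$Sigma[, , k], fit$model$D,
                              fit$model$D)))
})
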