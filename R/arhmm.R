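# --- design matrices ------------------------------------------------------

# AR design: row t (of the modeled range t = r+1 .. T) is
# [x_{t-1}, x_{t-2}, ..., x_{t-r}, 1].
build_ar_design <- function(Y, r) {
  T_ <- nrow(Y); D <- ncol(Y)
  stopifnot(T_ > r)
  X <- matrix(0, T_ - r, D * r + 1)
  for (l in seq_len(r))
    X[, ((l - 1) * D + 1):(l * D)] <- Y[(r + 1 - l):(T_ - l), , drop = FALSE]
  X[, D * r + 1] <- 1
  X
}

# Per-state Gaussian AR log-likelihood matrix, (T - r) x K.
state_loglik_matrix <- function(model, Y) {
  r <- model$ar_lag; D <- model$D; K <- model$K_max
  X <- build_ar_design(Y, r)
  Yt <- Y[(r + 1):nrow(Y), , drop = FALSE]
  out <- matrix(0, nrow(Yt), K)
  for (k in seq_len(K)) {
    B <- cbind(model$A[[k]], model$b[, k])
    Rm <- Yt - X %*% t(B)
    U <- tryCatch(chol(matrix(model$Sigma[, , k], D, D)),
                  error = function(e)
                    abort(sprintf("Sigma for state %d is not positive definite", k)))
    V <- backsolve(U, t(Rm), transpose = TRUE)  # U' V = R'
    quad <- colSums(V^2)
    out[, k] <- -0.5 * (D * log(2 * pi)) - sum(log(diag(U))) - 0.5 * quad
  }
  if (any(!is.finite(out))) abort("non-finite AR log-likelihood")
  out
}

#' Log density of one frame under one state's AR emission
#'
#' The last row of `window` is scored against the Gaussian whose mean is the
#' state's autoregression applied to the preceding `ar_lag` rows:
#' \eqn{N(\sum_l A_{k,l} x_{t-l} + b_k, \Sigma_k)}.
#'
#' @param model an [arhmm_model()].
#' @param state state index (1-based, <= `K_max`).
#' @param window (ar_lag + 1) x D matrix: the `ar_lag` lag frames in time
#'   order followed by the frame being scored.
#' @return scalar log density.
#' @export
ar_loglik <- function(model, state, window) {
  r <- model$ar_lag
  window <- as.matrix(window)
  if (state < 1 || state > model$K_max) abort("`state` out of range")
  if (nrow(window) != r + 1) abort("`window` must have ar_lag + 1 rows")
  if (any(!is.finite(window))) abort("`window` contains non-finite values")
  L <- state_loglik_matrix(model, window)
  L[1, state]
}

# --- label resampling -----------------------------------------------------

#' Draw per-frame labels from their exact conditional posterior
#'
#' Forward filtering with log-space normalized messages followed by
#' backward sampling, conditional on the model's dynamics and transition
#' matrix. The first `ar_lag` frames have no modeled likelihood and
#' inherit the label of the first modeled frame, so every frame carries
#' exactly one label.
#'
#' @param model an [arhmm_model()].
#' @param series a [pose_series()] (or numeric matrix).
#' @param seed RNG seed (`NULL` to continue the current RNG stream).
#' @return a [label_sequence()] over all frames.
#' @export
resample_labels <- function(model, series, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- series_values(series)
  r <- model$ar_lag
  if (nrow(Y) <= r) abort("series must be longer than the AR order")
  L <- state_loglik_matrix(model, Y)
  z <- ffbs_sample(log(model$pi), log(model$beta), L) + 1L
  label_sequence(c(rep(z[1], r), z), fps = series_fps(series))
}

series_values <- function(series) {
  if (inherits(series, "pose_series")) series$values else as.matrix(series)
}
series_fps <- function(series, default = 30) {
  if (inherits(series, "pose_series")) series$fps else default
}

# --- emission resampling --------------------------------------------------

# Matrix-normal / inverse-Wishart emission prior, matched to the data scale:
# identity scale on data standardized by the global variance is equivalent
# to an inverse-Wishart scale of (global variance) * I on the raw data.
emission_prior <- function(Y, r, nu0_extra = 1) {
  D <- ncol(Y)
  p <- D * r + 1
  s0 <- mean(apply(Y, 2, var))
  list(M0 = matrix(0, D, p), K0 = diag(p), S0 = diag(s0, D),
       nu0 = D + 1 + nu0_extra)
}

# One MNIW posterior draw for (B = [A b], Sigma) given rows (X, Y).
draw_mniw <- function(X, Yk, prior) {
  D <- nrow(prior$M0); p <- ncol(prior$M0)
  n <- if (is.null(X)) 0L else nrow(X)
  if (n > 0) {
    Kn <- prior$K0 + crossprod(X)
    Mn <- (prior$M0 %*% prior$K0 + crossprod(Yk, X)) %*% solve(Kn)
    Sn <- prior$S0 + crossprod(Yk) +
      prior$M0 %*% prior$K0 %*% t(prior$M0) - Mn %*% Kn %*% t(Mn)
    nun <- prior$nu0 + n
  } else {
    Kn <- prior$K0; Mn <- prior$M0; Sn <- prior$S0; nun <- prior$nu0
  }
  Sn <- (Sn + t(Sn)) / 2
  # guard tiny asymmetric round-off into indefiniteness
  Sn <- Sn + diag(1e-9 * mean(diag(Sn)), D)
  W <- rWishart(1, nun, solve(Sn))[, , 1]
  Sigma <- solve(W)
  Sigma <- (Sigma + t(Sigma)) / 2
  Ls <- t(chol(Sigma))
  Vn <- solve(Kn)
  Vn <- (Vn + t(Vn)) / 2
  Rv <- t(chol(Vn))
  B <- Mn + Ls %*% matrix(rnorm(D * p), D, p) %*% t(Rv)
  list(B = B, Sigma = Sigma)
}

#' Gibbs update of the per-state AR emission parameters
#'
#' Conjugate matrix-normal / inverse-Wishart posterior draw for each
#' state's lag matrices, offset and noise covariance, given the frames
#' currently assigned to it; states with no assigned frames draw from the
#' prior.
#'
#' @param series a [pose_series()] or matrix.
#' @param labels a [label_sequence()] (or vector) over all frames.
#' @param K_max truncation level.
#' @param ar_lag AR order.
#' @param prior list (M0, K0, S0, nu0) as built by the fitter; `NULL` uses
#'   the default prior computed from the series.
#' @param seed RNG seed (`NULL` to continue the current stream).
#' @return list with `A` (list of D x (D*ar_lag)), `b` (D x K) and `Sigma`
#'   (D x D x K).
#' @export
resample_emissions <- function(series, labels, K_max, ar_lag,
                               prior = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- series_values(series)
  z <- as_label_vector(labels)
  r <- ar_lag; D <- ncol(Y)
  stopifnot(length(z) == nrow(Y))
  if (is.null(prior)) prior <- emission_prior(Y, r)
  X <- build_ar_design(Y, r)
  Yt <- Y[(r + 1):nrow(Y), , drop = FALSE]
  zt <- z[(r + 1):length(z)]
  A <- vector("list", K_max)
  b <- matrix(0, D, K_max)
  Sigma <- array(0, c(D, D, K_max))
  for (k in seq_len(K_max)) {
    rows <- which(zt == k)
    draw <- if (length(rows) > 0) {
      draw_mniw(X[rows, , drop = FALSE], Yt[rows, , drop = FALSE], prior)
    } else {
      draw_mniw(NULL, NULL, prior)
    }
    A[[k]] <- draw$B[, seq_len(D * r), drop = FALSE]
    b[, k] <- draw$B[, D * r + 1]
    Sigma[, , k] <- draw$Sigma
  }
  list(A = A, b = b, Sigma = Sigma)
}

# --- transition resampling ------------------------------------------------

rdirichlet1 <- function(shape) {
  g <- rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[which.max(shape)] <- 1
  g / sum(g)
}

# CRF table counts: m = sum_{i=0}^{n-1} Bernoulli(c / (c + i)).
sample_table_count <- function(n, conc) {
  if (n == 0L) return(0L)
  sum(runif(n) < conc / (conc + seq_len(n) - 1))
}

#' Gibbs update of the sticky-HDP transition structure
#'
#' Counts transitions between consecutive labels, redraws each row of the
#' transition matrix from
#' Dirichlet(alpha * beta + kappa * e_j + counts), and updates the global
#' weights beta from auxiliary table counts (with the sticky correction
#' that discounts self-transition tables spawned by kappa) under the
#' top-level concentration gamma. This is the weak-limit finite-Dirichlet
#' approximation to the sticky hierarchical Dirichlet process.
#'
#' @param labels a [label_sequence()] or integer vector.
#' @param hdp list with `gamma`, `alpha`, `kappa`, `beta` (length K).
#' @param K_max truncation level.
#' @param seed RNG seed (`NULL` to continue the current stream).
#' @return list with updated `pi` (K x K) and `beta` (length K).
#' @export
resample_transitions <- function(labels, hdp, K_max, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- as_label_vector(labels)
  beta <- hdp$beta
  stopifnot(length(beta) == K_max)
  n <- matrix(0, K_max, K_max)
  if (length(z) >= 2) {
    from <- z[-length(z)]; to <- z[-1]
    n <- matrix(tabulate((to - 1L) * K_max + from, nbins = K_max * K_max),
                K_max, K_max)
  }
  # auxiliary table counts for the beta update
  m <- matrix(0L, K_max, K_max)
  for (j in seq_len(K_max)) {
    for (k in which(n[j, ] > 0)) {
      conc <- hdp$alpha * beta[k] + if (j == k) hdp$kappa else 0
      m[j, k] <- sample_table_count(n[j, k], conc)
    }
  }
  # sticky correction: tables at (j, j) opened by the kappa mass do not
  # inform beta
  if (hdp$kappa > 0) {
    rho <- hdp$kappa / (hdp$alpha + hdp$kappa)
    for (j in seq_len(K_max)) {
      if (m[j, j] > 0) {
        p_override <- rho / (rho + beta[j] * (1 - rho))
        w <- rbinom(1, m[j, j], p_override)
        m[j, j] <- m[j, j] - w
      }
    }
  }
  beta_new <- rdirichlet1(hdp$gamma / K_max + colSums(m))
  pi_new <- t(vapply(seq_len(K_max), function(j) {
    shape <- hdp$alpha * beta_new + n[j, ]
    shape[j] <- shape[j] + hdp$kappa
    rdirichlet1(shape)
  }, numeric(K_max)))
  list(pi = pi_new, beta = beta_new)
}

#' Sticky mass for a target mean syllable duration
#'
#' Under the sticky prior the expected self-transition probability is
#' roughly `kappa / (alpha + kappa)`, giving geometric dwell with mean
#' `d = 1 + kappa / alpha` frames; inverting gives
#' `kappa = alpha * (d - 1)` for a target dwell of `d` frames. This is the
#' single knob that sets the timescale at which the model looks for
#' behavioral structure (roughly 100 ms to over a second).
#'
#' @param target_mean_duration_s target mean syllable duration in seconds.
#' @param fps frame rate.
#' @param alpha per-row Dirichlet concentration.
#' @return kappa (non-negative scalar).
#' @export
mean_duration_to_kappa <- function(target_mean_duration_s, fps, alpha) {
  stopifnot(target_mean_duration_s > 0, fps > 0, alpha > 0)
  d <- target_mean_duration_s * fps
  if (d <= 1)
    abort("target duration must exceed one frame at this frame rate")
  alpha * (d - 1)
}

# --- full fit -------------------------------------------------------------

joint_logprob <- function(L, z_eff, logpi, logbeta) {
  ll <- sum(L[cbind(seq_along(z_eff), z_eff)])
  trans <- sum(logpi[cbind(z_eff[-length(z_eff)], z_eff[-1])])
  ll + trans + logbeta[z_eff[1]]
}

series_checksum <- function(series) {
  Y <- series_values(series)
  sprintf("%dx%d|%.12e|%.12e", nrow(Y), ncol(Y), sum(Y), sum(Y * Y))
}

#' Fit the sticky HDP-AR-HMM by Gibbs sampling
#'
#' Alternates exact conditional draws of the label sequence (forward
#' filtering / backward sampling), the per-state AR emission parameters
#' (matrix-normal / inverse-Wishart), and the sticky-HDP transition
#' structure. The number of used states is not fixed: the weak-limit HDP
#' prior lets occupied states grow with the data. Returns the final
#' post-burn-in sample with states relabeled in descending usage order.
#'
#' @param series a [pose_series()] (or numeric matrix; frame rate then
#'   defaults to 30).
#' @param config a [fit_config()].
#' @return An object of class `arhmm_fit`: `model` (an [arhmm_model()]),
#'   `labels` (a [label_sequence()]), `diagnostics` (tibble with per-sweep
#'   joint log probability and used-state count), `config`, and the
#'   training-series checksum.
#' @export
fit_arhmm <- function(series, config = fit_config()) {
  Y <- series_values(series)
  fps <- series_fps(series)
  r <- config$ar_lag; K <- config$K_max; D <- ncol(Y)
  if (nrow(Y) <= r * 10)
    abort("series too short to identify AR dynamics")
  kappa <- config$kappa %||%
    mean_duration_to_kappa(config$target_mean_duration_s, fps, config$alpha)
  prior <- emission_prior(Y, r, config$nu0_extra)
  set.seed(config$seed)

  # initialization: uniform random labels, prior-mean-ish transitions
  T_eff <- nrow(Y) - r
  z <- sample.int(K, nrow(Y), replace = TRUE)
  beta <- rep(1 / K, K)
  hdp <- list(gamma = config$gamma, alpha = config$alpha, kappa = kappa,
              beta = beta)
  em <- resample_emissions(Y, z, K, r, prior = prior)
  tr <- resample_transitions(z, hdp, K)
  diagnostics <- tibble(sweep = integer(), joint_logprob = numeric(),
                        n_used_states = integer())
  model <- NULL
  for (s in seq_len(config$n_sweeps)) {
    model <- arhmm_model(A = em$A, b = em$b, Sigma = em$Sigma, pi = tr$pi,
                         beta = tr$beta, ar_lag = r, gamma = config$gamma,
                         alpha = config$alpha, kappa = kappa, fps = fps)
    L <- state_loglik_matrix(model, Y)
    z_eff <- ffbs_sample(log(model$pi), log(model$beta), L) + 1L
    z <- c(rep(z_eff[1], r), z_eff)
    jlp <- joint_logprob(L, z_eff, log(model$pi), log(model$beta))
    if (!is.finite(jlp))
      abort(sprintf("sampler diverged: non-finite joint log probability at sweep %d", s))
    diagnostics <- dplyr::bind_rows(diagnostics, tibble(
      sweep = s, joint_logprob = jlp,
      n_used_states = length(unique(z_eff))))
    em <- resample_emissions(Y, z, K, r, prior = prior)
    hdp$beta <- tr$beta
    tr <- resample_transitions(z, hdp, K)
  }
  # final model uses the last parameter draws, relabeled by usage
  model <- arhmm_model(A = em$A, b = em$b, Sigma = em$Sigma, pi = tr$pi,
                       beta = tr$beta, ar_lag = r, gamma = config$gamma,
                       alpha = config$alpha, kappa = kappa, fps = fps)
  out <- relabel_by_usage(model, z)
  structure(
    list(model = out$model,
         labels = label_sequence(out$labels, fps = fps),
         diagnostics = diagnostics, config = config,
         train_checksum = series_checksum(series)),
    class = "arhmm_fit")
}

# Reorder states so state 1 is the most-used; parameters, transition rows
# and columns, and beta follow the permutation.
relabel_by_usage <- function(model, labels) {
  K <- model$K_max
  counts <- tabulate(labels, nbins = K)
  ord <- order(counts, decreasing = TRUE)
  inv <- integer(K); inv[ord] <- seq_len(K)
  new_model <- arhmm_model(
    A = model$A[ord], b = model$b[, ord, drop = FALSE],
    Sigma = model$Sigma[, , ord, drop = FALSE],
    pi = model$pi[ord, ord, drop = FALSE], beta = model$beta[ord],
    ar_lag = model$ar_lag, gamma = model$hdp$gamma, alpha = model$hdp$alpha,
    kappa = model$hdp$kappa, fps = model$fps)
  list(model = new_model, labels = inv[labels])
}

#' @export
print.arhmm_fit <- function(x, ...) {
  used <- length(unique(x$labels$labels))
  cat(sprintf("<arhmm_fit> %d frames, %d used states (K_max=%d), %d sweeps\n",
              x$labels$T, used, x$model$K_max, x$config$n_sweeps))
  invisible(x)
}

# --- held-out likelihood --------------------------------------------------

#' Log marginal likelihood of a series under a fitted model
#'
#' Labels are summed out by the forward algorithm on log-space normalized
#' messages, so the result is the model's predictive score for the series.
#' Generic so switching models and baselines can be ranked on the same
#' held-out frames.
#'
#' @param model a fitted model (an [arhmm_model()], `arhmm_fit`, or
#'   baseline object).
#' @param series a [pose_series()] or matrix, not used in fitting.
#' @param ... passed to methods.
#' @return scalar total log likelihood.
#' @export
heldout_loglik <- function(model, series, ...) UseMethod("heldout_loglik")

#' @export
heldout_loglik.arhmm <- function(model, series, ...) {
  Y <- series_values(series)
  if (nrow(Y) <= model$ar_lag)
    abort("series must be longer than the AR order")
  L <- state_loglik_matrix(model, Y)
  ll <- forward_loglik(log(model$pi), log(model$beta), L)
  if (!is.finite(ll)) abort("non-finite held-out log likelihood")
  ll
}

#' @export
heldout_loglik.arhmm_fit <- function(model, series, ...)
  heldout_loglik(model$model, series, ...)
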