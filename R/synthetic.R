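#' Sample a sticky Markov state sequence
#'
#' Self-transition probability is `1 - 1/mean_duration_frames`, giving
#' geometric dwell times with the requested mean; remaining mass is spread
#' uniformly over the other states.
#'
#' @param n_states number of states.
#' @param mean_duration_frames expected dwell time in frames (> 1).
#' @param n_frames length of the sequence.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return integer vector of 1-based states.
#' @export
sample_sticky_chain <- function(n_states, mean_duration_frames, n_frames,
                                seed = NULL) {
  if (mean_duration_frames <= 1) abort("`mean_duration_frames` must be > 1")
  if (!is.null(seed)) set.seed(seed)
  if (n_states == 1L) return(rep(1L, n_frames))
  p_self <- 1 - 1 / mean_duration_frames
  z <- integer(n_frames)
  t <- 1L
  z[1] <- sample.int(n_states, 1)
  # draw geometric dwell lengths rather than looping per frame
  repeat {
    run <- 1L + stats::rgeom(1, 1 - p_self)
    z[t:min(n_frames, t + run - 1L)] <- z[t]
    if (t + run > n_frames) break
    nxt <- sample.int(n_states - 1L, 1)
    z[t + run] <- if (nxt >= z[t]) nxt + 1L else nxt
    t <- t + run
  }
  z
}

# Random D x D orthogonal matrix (QR of a Gaussian matrix with sign fix).
random_orthogonal <- function(D) {
  if (D == 1L) return(matrix(sample(c(-1, 1), 1), 1, 1))
  qr_ <- qr(matrix(rnorm(D * D), D))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), D)
}

# Scale lag matrices so the companion matrix has spectral radius <= rho_max.
# Scaling A_l by s^l scales every companion eigenvalue by s exactly.
stabilize_lags <- function(A_lags, rho_max = 0.99) {
  D <- nrow(A_lags[[1]])
  r <- length(A_lags)
  comp <- matrix(0, D * r, D * r)
  for (l in seq_len(r)) comp[1:D, ((l - 1) * D + 1):(l * D)] <- A_lags[[l]]
  if (r > 1) comp[(D + 1):(D * r), 1:(D * (r - 1))] <- diag(D * (r - 1))
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (sr > rho_max) {
    s <- rho_max / sr
    A_lags <- lapply(seq_len(r), function(l) A_lags[[l]] * s^l)
  }
  A_lags
}

# Draw one state's stable AR dynamics: a rotation-plus-contraction lag-1
# matrix, small higher lags, and an offset placing the fixed point at `mu`.
random_state_dynamics <- function(D, r, mu, contraction = NULL) {
  if (is.null(contraction)) contraction <- runif(1, 0.90, 0.97)
  A <- vector("list", r)
  A[[1]] <- contraction * random_orthogonal(D)
  if (r > 1) {
    for (l in 2:r) A[[l]] <- matrix(rnorm(D * D, sd = 0.05 / sqrt(D)), D)
  }
  A <- stabilize_lags(A)
  Asum <- Reduce(`+`, A)
  b <- as.numeric((diag(D) - Asum) %*% mu)
  list(A = do.call(cbind, A), b = b)
}

#' Simulate a pose series from an AR-HMM
#'
#' Runs the generative model forward: optionally samples a state sequence
#' from the model's transition matrix, then emits
#' \eqn{x_t = \sum_l A_{k,l} x_{t-l} + b_k + \epsilon_t}.
#'
#' @param model an [arhmm_model()].
#' @param n_frames number of frames to generate.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param labels optional fixed state sequence (length `n_frames`); if
#'   `NULL`, sampled from `model$pi` starting from `model$beta`.
#' @param x0 optional `ar_lag` x D matrix of initial frames.
#' @param noise_scale if `NULL` (default) noise is drawn from each state's
#'   `Sigma`; a scalar overrides with isotropic noise of that standard
#'   deviation (0 gives a noiseless trajectory).
#' @return list with `series` (a [pose_series()]) and `labels`.
#' @export
simulate_arhmm <- function(model, n_frames, seed = NULL, labels = NULL,
                           x0 = NULL, noise_scale = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- model$D; r <- model$ar_lag; K <- model$K_max
  if (n_frames <= r) abort("`n_frames` must exceed the AR order")
  if (is.null(labels)) {
    labels <- integer(n_frames)
    labels[1] <- sample.int(K, 1, prob = model$beta)
    for (t in 2:n_frames)
      labels[t] <- sample.int(K, 1, prob = model$pi[labels[t - 1], ])
  }
  stopifnot(length(labels) == n_frames, all(labels >= 1), all(labels <= K))
  chol_S <- lapply(seq_len(K), function(k)
    chol(matrix(model$Sigma[, , k], D, D)))
  X <- matrix(0, n_frames, D)
  if (is.null(x0)) {
    X[seq_len(r), ] <- matrix(rnorm(r * D, sd = 0.1), r, D)
  } else {
    stopifnot(nrow(x0) == r, ncol(x0) == D)
    X[seq_len(r), ] <- x0
  }
  for (t in (r + 1):n_frames) {
    k <- labels[t]
    lagvec <- as.numeric(t(X[t - seq_len(r), , drop = FALSE]))
    mu <- as.numeric(model$A[[k]] %*% lagvec) + model$b[, k]
    eps <- if (is.null(noise_scale)) {
      as.numeric(t(chol_S[[k]]) %*% rnorm(D))
    } else if (noise_scale == 0) {
      rep(0, D)
    } else {
      rnorm(D, sd = noise_scale)
    }
    X[t, ] <- mu + eps
    if (any(!is.finite(X[t, ])) || any(abs(X[t, ]) > 1e8))
      abort(sprintf(
        "unstable dynamics: non-finite trajectory at frame %d in state %d",
        t, k))
  }
  list(series = pose_series(X, fps = model$fps, source = "synthetic"),
       labels = as.integer(labels))
}

#' Generate an AR-HMM pose series with known ground truth
#'
#' Draws a random switching linear-dynamical model — per-state
#' rotation-plus-contraction lag matrices scaled to spectral radius at most
#' 0.99, state fixed points spread in pose space, isotropic Gaussian noise —
#' samples a sticky Markov state sequence with geometric dwell of the given
#' mean, and runs the dynamics forward. The returned ground truth carries
#' the per-frame labels and the exact generating model.
#'
#' @param n_states number of latent states (>= 1).
#' @param dim pose-space dimension D.
#' @param ar_lag AR order (>= 1).
#' @param mean_duration_frames expected state dwell in frames (> 1).
#' @param n_frames series length (> `ar_lag`).
#' @param noise_scale emission noise standard deviation.
#' @param seed RNG seed.
#' @param separation standard deviation of the state fixed points; larger
#'   values give more separable states.
#' @param fps nominal frame rate recorded in the series.
#' @return list with `series` (a [pose_series()]) and `truth` (a
#'   `ground_truth` with `true_labels`, `true_params`, `seed`).
#' @export
generate_arhmm_series <- function(n_states, dim, ar_lag = 1,
                                  mean_duration_frames, n_frames,
                                  noise_scale = 0.1, seed = 1,
                                  separation = 4, fps = 30) {
  stopifnot(n_states >= 1, dim >= 1, ar_lag >= 1,
            mean_duration_frames > 1, n_frames > ar_lag)
  set.seed(seed)
  K <- n_states; D <- dim; r <- ar_lag
  mus <- matrix(rnorm(K * D, sd = separation), K, D)
  dyn <- lapply(seq_len(K), function(k) random_state_dynamics(D, r, mus[k, ]))
  A <- lapply(dyn, `[[`, "A")
  b <- vapply(dyn, `[[`, numeric(D), "b")
  b <- matrix(b, nrow = D)
  Sigma <- array(0, c(D, D, K))
  for (k in seq_len(K))
    Sigma[, , k] <- diag(max(noise_scale, 1e-6)^2, D)
  p_self <- 1 - 1 / mean_duration_frames
  pi_mat <- if (K == 1) matrix(1, 1, 1) else {
    m <- matrix((1 - p_self) / (K - 1), K, K)
    diag(m) <- p_self
    m
  }
  model <- arhmm_model(A = A, b = b, Sigma = Sigma, pi = pi_mat,
                       beta = rep(1 / K, K), ar_lag = r, kappa = 0,
                       fps = fps)
  z <- sample_sticky_chain(K, mean_duration_frames, n_frames, seed = NULL)
  sim <- simulate_arhmm(model, n_frames, seed = NULL, labels = z,
                        noise_scale = noise_scale)
  truth <- structure(list(true_labels = sim$labels, true_params = model,
                          seed = seed),
                     class = "ground_truth")
  list(series = sim$series, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames, %d states, seed %d\n",
              length(x$true_labels), x$true_params$K_max, x$seed))
  invisible(x)
}

#' Generate a module-free control series
#'
#' A single slowly varying stable AR(1) regime with no switching: the
#' autocorrelation decays smoothly and there are no change points. Used as
#' the control input for the "does the model invent modules?" analysis.
#'
#' @param dim pose-space dimension.
#' @param n_frames series length (>= 2).
#' @param smoothness AR(1) coefficient in (0, 1); closer to 1 is smoother.
#' @param seed RNG seed.
#' @param noise_scale stationary standard deviation of each component.
#' @param fps nominal frame rate.
#' @return a [pose_series()].
#' @export
generate_nonmodular_series <- function(dim, n_frames, smoothness = 0.98,
                                       seed = 1, noise_scale = 1, fps = 30) {
  stopifnot(dim >= 1, n_frames >= 2, smoothness > 0, smoothness < 1)
  set.seed(seed)
  s <- smoothness
  innov_sd <- noise_scale * sqrt(1 - s^2)
  X <- matrix(0, n_frames, dim)
  X[1, ] <- rnorm(dim, sd = noise_scale)
  eps <- matrix(rnorm((n_frames - 1) * dim, sd = innov_sd), n_frames - 1, dim)
  for (t in 2:n_frames) X[t, ] <- s * X[t - 1, ] + eps[t - 1, ]
  if (any(!is.finite(X))) abort("non-finite trajectory in control series")
  pose_series(X, fps = fps, source = "synthetic")
}
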