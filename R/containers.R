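#' Pose-dynamics time series
#'
#' The low-dimensional representation of aligned pose video consumed by the
#' autoregressive model: a numeric matrix with one row per frame and one
#' column per component, tagged with its frame rate and provenance.
#'
#' @param values numeric matrix, frames by components (T x D).
#' @param fps frames per second of the underlying recording.
#' @param source one of `"pca"`, `"random_projection"`, `"synthetic"`.
#' @param basis optional D x P projection matrix (rows are components,
#'   columns are pixels) used to produce `values`.
#' @param explained_variance optional per-component variance fractions
#'   (PCA only); must be non-increasing and sum to at most 1.
#'
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(values, fps,
                        source = c("synthetic", "pca", "random_projection"),
                        basis = NULL, explained_variance = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) < 1)
    abort("`values` must be a numeric matrix with at least one column")
  if (any(!is.finite(values)))
    abort("`values` contains non-finite entries")
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be positive")
  if (!is.null(explained_variance)) {
    if (any(diff(explained_variance) > 1e-12))
      abort("`explained_variance` must be non-increasing")
    if (sum(explained_variance) > 1 + 1e-8)
      abort("`explained_variance` must sum to at most 1")
  }
  if (!is.null(basis) && source == "pca") {
    g <- basis %*% t(basis)
    if (max(abs(g - diag(nrow(basis)))) > 1e-8)
      abort("PCA basis rows must be orthonormal")
  }
  structure(
    list(values = unname(values), fps = fps, source = source,
         basis = basis, explained_variance = explained_variance),
    class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d frames x %d components, %g fps, source: %s\n",
              nrow(x$values), ncol(x$values), x$fps, x$source))
  invisible(x)
}

#' @export
dim.pose_series <- function(x) dim(x$values)

#' @rdname pose_series
#' @param x a `pose_series`.
#' @param ... unused.
#' @export
as_tibble.pose_series <- function(x, ...) {
  d <- as_tibble(x$values, .name_repair = ~ paste0("pc", seq_along(.x)))
  dplyr::mutate(d,
    frame = dplyr::row_number(),
    time_s = (.data$frame - 1) / x$fps,
    .before = 1)
}

#' Per-frame syllable labels
#'
#' Every frame of a modeled recording carries exactly one syllable label;
#' there are no gaps. Labels are positive integers below the model's
#' truncation level.
#'
#' @param labels integer vector of per-frame state IDs (1-based).
#' @param fps frames per second.
#' @param model_id optional identifier of the model that produced the labels.
#'
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels, fps, model_id = NA_character_) {
  labels <- as.integer(labels)
  if (length(labels) == 0) abort("`labels` must be non-empty")
  if (anyNA(labels)) abort("`labels` must not contain NA: every frame is assigned")
  if (any(labels < 1L)) abort("labels are 1-based positive integers")
  structure(list(labels = labels, T = length(labels), fps = fps,
                 model_id = model_id),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d frames, %d used syllables, %g fps\n",
              x$T, length(unique(x$labels)), x$fps))
  invisible(x)
}

#' @rdname label_sequence
#' @param x a `label_sequence`.
#' @param ... unused.
#' @export
as_tibble.label_sequence <- function(x, ...) {
  tibble(frame = seq_len(x$T), state = x$labels)
}

# Accept a label_sequence, a data frame with a `state` column, or a bare
# integer vector wherever labels are consumed.
as_label_vector <- function(labels) {
  if (inherits(labels, "label_sequence")) return(labels$labels)
  if (is.data.frame(labels)) {
    if (!"state" %in% names(labels))
      abort("label data frame must have a `state` column")
    return(as.integer(labels$state))
  }
  as.integer(labels)
}

labels_fps <- function(labels, fps = NULL) {
  if (!is.null(fps)) return(fps)
  if (inherits(labels, "label_sequence")) return(labels$fps)
  abort("`fps` must be supplied when labels are not a label_sequence")
}

#' Sticky HDP autoregressive hidden Markov model
#'
#' The generative model of behavior: each syllable k is a linear
#' autoregressive Gaussian regime
#' \eqn{x_t = \sum_l A_{k,l} x_{t-l} + b_k + \epsilon_t},
#' \eqn{\epsilon_t \sim N(0, \Sigma_k)}, and syllables follow each other
#' according to a Markov transition matrix drawn from a (weak-limit
#' truncated) hierarchical Dirichlet process with an extra sticky mass
#' `kappa` on self-transitions that sets the dwell timescale.
#'
#' @param A list of K lag matrices, each D x (D*ar_lag).
#' @param b D x K matrix of per-state offsets.
#' @param Sigma D x D x K array of noise covariances (each symmetric
#'   positive definite).
#' @param pi K x K row-stochastic transition matrix.
#' @param beta length-K global state weights (sums to 1).
#' @param ar_lag autoregressive order r (number of lags).
#' @param gamma,alpha,kappa HDP concentrations: top level, per row, and
#'   sticky self-transition mass.
#' @param fps frames per second the model was fit at.
#'
#' @return An object of class `arhmm`.
#' @export
arhmm_model <- function(A, b, Sigma, pi, beta, ar_lag,
                        gamma = 10, alpha = 5, kappa = 0, fps = 30) {
  K <- length(A)
  D <- nrow(A[[1]])
  b <- as.matrix(b)
  stopifnot(ncol(b) == K, nrow(b) == D, dim(Sigma)[3] == K)
  pi <- as.matrix(pi)
  if (nrow(pi) != K || ncol(pi) != K) abort("`pi` must be K x K")
  if (max(abs(rowSums(pi) - 1)) > 1e-10)
    abort("each row of `pi` must sum to 1")
  if (abs(sum(beta) - 1) > 1e-10) abort("`beta` must sum to 1")
  if (kappa < 0 || gamma <= 0 || alpha <= 0)
    abort("require kappa >= 0 and gamma, alpha > 0")
  for (k in seq_len(K)) {
    S <- Sigma[, , k, drop = TRUE]
    S <- matrix(S, D, D)
    if (max(abs(S - t(S))) > 1e-8) abort(sprintf("Sigma[%d] not symmetric", k))
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) abort(sprintf("Sigma[%d] not positive definite", k))
    if (ncol(A[[k]]) != D * ar_lag)
      abort(sprintf("A[[%d]] must be D x (D*ar_lag)", k))
  }
  structure(
    list(K_max = K, D = D, ar_lag = ar_lag,
         A = A, b = b, Sigma = Sigma, pi = pi, beta = as.numeric(beta),
         hdp = list(gamma = gamma, alpha = alpha, kappa = kappa),
         fps = fps),
    class = "arhmm")
}

#' @export
print.arhmm <- function(x, ...) {
  cat(sprintf(
    "<arhmm> K_max=%d, D=%d, ar_lag=%d, kappa=%g (gamma=%g, alpha=%g)\n",
    x$K_max, x$D, x$ar_lag, x$hdp$kappa, x$hdp$gamma, x$hdp$alpha))
  invisible(x)
}

#' Fit configuration for the Gibbs sampler
#'
#' @param n_sweeps total Gibbs sweeps.
#' @param n_burnin sweeps discarded as burn-in (must be < `n_sweeps`).
#' @param seed RNG seed; every random draw in the fit flows from it.
#' @param target_mean_duration_s prior target for mean syllable duration in
#'   seconds; sets the sticky mass via [mean_duration_to_kappa()]. The prior
#'   is flexible: it admits syllables from around a hundred milliseconds to
#'   more than a second.
#' @param K_max weak-limit truncation level (maximum number of states).
#' @param ar_lag autoregressive order.
#' @param gamma,alpha HDP concentration parameters (top level / per row).
#' @param kappa sticky self-transition mass; if `NULL`, derived from
#'   `target_mean_duration_s` at fit time.
#' @param nu0_extra inverse-Wishart degrees of freedom above D + 1 for the
#'   emission noise prior (default 1, i.e. nu0 = D + 2).
#'
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_sweeps = 100, n_burnin = 50, seed = 1,
                       target_mean_duration_s = 0.3,
                       K_max = 100, ar_lag = 3,
                       gamma = 10, alpha = 5, kappa = NULL,
                       nu0_extra = 1) {
  if (n_burnin >= n_sweeps) abort("`n_burnin` must be < `n_sweeps`")
  if (target_mean_duration_s <= 0)
    abort("`target_mean_duration_s` must be positive")
  structure(
    list(n_sweeps = as.integer(n_sweeps), n_burnin = as.integer(n_burnin),
         seed = as.integer(seed),
         target_mean_duration_s = target_mean_duration_s,
         K_max = as.integer(K_max), ar_lag = as.integer(ar_lag),
         gamma = gamma, alpha = alpha, kappa = kappa,
         nu0_extra = nu0_extra),
    class = "fit_config")
}
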