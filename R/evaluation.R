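#' Single-state continuous AR baseline
#'
#' The "behavior is continuous" null model: one linear-Gaussian
#' autoregression fit to the whole training series by least squares with
#' its maximum-likelihood noise covariance (lightly ridged for numerical
#' safety). Represented as a one-state [arhmm_model()] so it is scored by
#' the same [heldout_loglik()] path as the switching model.
#'
#' @param train a [pose_series()] or matrix.
#' @param ar_lag AR order.
#' @return An `arhmm_fit`-like object of class `ar_baseline` with `model`
#'   and `train_checksum`.
#' @export
ar_baseline <- function(train, ar_lag = 3) {
  Y <- series_values(train)
  r <- ar_lag; D <- ncol(Y)
  X <- build_ar_design(Y, r)
  Yt <- Y[(r + 1):nrow(Y), , drop = FALSE]
  XtX <- crossprod(X) + diag(1e-8, ncol(X))
  B <- t(solve(XtX, crossprod(X, Yt)))          # D x (D*r + 1)
  Rm <- Yt - X %*% t(B)
  Sigma <- crossprod(Rm) / nrow(Rm) + diag(1e-8 * mean(Rm^2) + 1e-12, D)
  model <- arhmm_model(
    A = list(B[, seq_len(D * r), drop = FALSE]),
    b = matrix(B[, D * r + 1], D, 1),
    Sigma = array(Sigma, c(D, D, 1)),
    pi = matrix(1, 1, 1), beta = 1, ar_lag = r,
    fps = series_fps(train))
  structure(list(model = model, train_checksum = series_checksum(train)),
            class = "ar_baseline")
}

#' @export
heldout_loglik.ar_baseline <- function(model, series, ...)
  heldout_loglik(model$model, series, ...)

#' Gaussian-mixture-over-frames baseline
#'
#' Clusters training frames with a Gaussian mixture (no temporal
#' structure) and scores held-out frames by the mixture density — the
#' classic "just cluster the data" alternative the switching AR model is
#' compared against. Fitting is delegated to mclust; degenerate
#' covariance collapse is avoided by falling back to progressively more
#' constrained covariance families, and any fallback is recorded.
#'
#' @param train,test [pose_series()] or matrices.
#' @param n_components number of mixture components.
#' @param seed RNG seed (mclust initialization is deterministic, but the
#'   seed is set for reproducibility of any stochastic fallback path).
#' @return An object of class `gmm_baseline`: total and per-frame held-out
#'   log likelihood, the fitted mixture, the covariance family used.
#' @export
gmm_baseline <- function(train, test, n_components, seed = 1) {
  if (n_components < 1) abort("`n_components` must be >= 1")
  set.seed(seed)
  Ytr <- series_values(train); Yte <- series_values(test)
  # Mclust resolves mclustBIC in the calling frame; bind it locally so the
  # package need not be attached
  mclustBIC <- mclust::mclustBIC
  fit <- NULL; family_used <- NA_character_
  for (fam in c("VVV", "VVI", "EEE", "EII")) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(Ytr, G = n_components,
                                      modelNames = fam, verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik)) { family_used <- fam; break }
  }
  if (is.null(fit)) abort("Gaussian mixture fit failed for every covariance family")
  ll <- mclust::dens(Yte, fit$modelName, parameters = fit$parameters,
                     logarithm = TRUE)
  total <- sum(ll)
  if (!is.finite(total)) abort("non-finite mixture held-out log likelihood")
  structure(list(total_loglik = total, per_frame = total / nrow(Yte),
                 fit = fit, family = family_used,
                 n_components = n_components,
                 train_checksum = series_checksum(train),
                 test_checksum = series_checksum(test)),
            class = "gmm_baseline")
}

#' @export
heldout_loglik.gmm_baseline <- function(model, series, ...) {
  ll <- mclust::dens(series_values(series), model$fit$modelName,
                     parameters = model$fit$parameters, logarithm = TRUE)
  sum(ll)
}

#' Held-out model comparison
#'
#' Scores every fitted model on the same held-out frames by total and
#' per-frame log likelihood and records the ranking. Trained generative
#' models make quantitative predictions about held-out data, so this is
#' the yardstick by which model classes (switching AR, continuous AR,
#' frame mixture) are compared. All models must have been fit on `train`;
#' a checksum mismatch is an error.
#'
#' @param train the training series the models were fit on.
#' @param test held-out series, disjoint from `train`.
#' @param models named list of fitted models (each with a
#'   [heldout_loglik()] method and a `train_checksum`).
#' @return An `eval_report` tibble: `model`, `total_loglik`,
#'   `per_frame_loglik`, `n_used_states`; attribute `test_checksum`.
#' @export
heldout_compare <- function(train, test, models) {
  if (is.null(names(models)) || any(names(models) == ""))
    abort("`models` must be a named list")
  tr_sum <- series_checksum(train)
  te_sum <- series_checksum(test)
  if (identical(tr_sum, te_sum)) abort("`train` and `test` are identical")
  rows <- purrr::imap(models, function(m, nm) {
    if (!is.null(m$train_checksum) && !identical(m$train_checksum, tr_sum))
      abort(sprintf("model '%s' was not fit on `train` (checksum mismatch)", nm))
    total <- heldout_loglik(m, test)
    used <- if (inherits(m, "arhmm_fit"))
      length(unique(m$labels$labels)) else if (inherits(m, "gmm_baseline"))
        m$n_components else 1L
    tibble(model = nm, total_loglik = total,
           per_frame_loglik = total / nrow(series_values(test)),
           n_used_states = as.integer(used))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$per_frame_loglik))
  out$rank <- seq_len(nrow(out))
  if (any(!is.finite(out$total_loglik))) abort("non-finite score in report")
  attr(out, "test_checksum") <- te_sum
  class(out) <- c("eval_report", class(out))
  out
}

#' Does the model invent modules where none exist?
#'
#' Fits the switching model to a modular series and to a deliberately
#' module-free control series, then reports, for each, the number of
#' effective states (states covering at least `effective_frac` of frames)
#' and the largest state's frame share. The verdict is "no imposed
#' structure" when the control collapses onto one dominant state
#' (share > `share_threshold`) while the modular input still yields at
#' least `min_effective_states` effective states.
#'
#' @param modular,nonmodular [pose_series()] of the same dimension.
#' @param config a [fit_config()].
#' @param effective_frac frame-share threshold defining an effective state.
#' @param share_threshold largest-state share above which the control is
#'   judged structureless.
#' @param min_effective_states minimum effective states expected on the
#'   modular input.
#' @return list with per-input tibbles and the logical
#'   `no_imposed_structure` verdict.
#' @export
cross_likelihood_control <- function(modular, nonmodular,
                                     config = fit_config(),
                                     effective_frac = 0.01,
                                     share_threshold = 0.9,
                                     min_effective_states = 4) {
  if (ncol(series_values(modular)) != ncol(series_values(nonmodular)))
    abort("the two series must have the same dimension")
  describe <- function(fit) {
    u <- usages(fit$labels)
    tibble(n_effective_states = sum(u$usage >= effective_frac),
           largest_state_share = max(u$usage),
           n_used_states = nrow(u))
  }
  fit_mod <- fit_arhmm(modular, config)
  fit_non <- fit_arhmm(nonmodular, config)
  d_mod <- describe(fit_mod); d_non <- describe(fit_non)
  verdict <- d_non$largest_state_share > share_threshold &&
    d_mod$n_effective_states >= min_effective_states
  list(modular = d_mod, nonmodular = d_non,
       no_imposed_structure = verdict,
       effective_frac = effective_frac,
       share_threshold = share_threshold,
       min_effective_states = min_effective_states,
       fits = list(modular = fit_mod, nonmodular = fit_non))
}

#' Used-state count as a function of data volume
#'
#' Fits the model to nested prefixes of a series and reports the number of
#' used states per prefix, with the sublinearity statistic: the maximum
#' over consecutive fraction pairs of (state-count ratio) / (data-size
#' ratio). Under the HDP prior the discovered repertoire grows sublinearly
#' with data, so the statistic should fall below 1.
#'
#' @param series a [pose_series()].
#' @param fractions increasing data fractions in (0, 1].
#' @param config a [fit_config()].
#' @param effective_frac frame share defining a used (effective) state.
#' @return tibble with `fraction`, `n_frames`, `used_states`; attribute
#'   `sublinearity` and `skipped` (fractions too short to fit).
#' @export
state_count_curve <- function(series, fractions = c(0.125, 0.25, 0.5, 1),
                              config = fit_config(),
                              effective_frac = 0.01) {
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1))
    abort("`fractions` must be increasing, in (0, 1]")
  Y <- series_values(series)
  fps <- series_fps(series)
  rows <- list(); skipped <- numeric()
  for (f in fractions) {
    n <- floor(f * nrow(Y))
    if (n <= config$ar_lag * 10) {
      message(sprintf("fraction %g gives %d frames: too short, skipped", f, n))
      skipped <- c(skipped, f)
      next
    }
    prefix <- pose_series(Y[seq_len(n), , drop = FALSE], fps = fps,
                          source = "synthetic")
    fit <- fit_arhmm(prefix, config)
    u <- usages(fit$labels)
    rows[[length(rows) + 1]] <- tibble(
      fraction = f, n_frames = n,
      used_states = sum(u$usage >= effective_frac))
  }
  out <- dplyr::bind_rows(rows)
  subl <- NA_real_
  if (nrow(out) >= 2) {
    cr <- out$used_states[-1] / out$used_states[-nrow(out)]
    dr <- out$n_frames[-1] / out$n_frames[-nrow(out)]
    subl <- max(cr / dr)
  }
  attr(out, "sublinearity") <- subl
  attr(out, "skipped") <- skipped
  out
}
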