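# Flatten crops to a frames x pixels matrix (row-major over the crop).
flatten_crops <- function(video) {
  d <- dim(video$crops)
  matrix(video$crops, d[1], d[2] * d[3])
}

# Linear interpolation over invalid frames, per column; endpoints extended.
interp_invalid <- function(scores, valid) {
  if (all(valid)) return(scores)
  t_all <- seq_len(nrow(scores))
  apply(scores, 2, function(col)
    approx(t_all[valid], col[valid], xout = t_all, rule = 2)$y)
}

#' Principal-component compression of aligned pose video
#'
#' Mean-centers the pixel vectors of the valid crops and projects them onto
#' the top principal axes. Depth data are strongly low-dimensional, and
#' with an overhead camera the first principal component tracks movement
#' along the z-axis (e.g. rearing). Invalid frames are filled by linear
#' interpolation in component space so the time base stays uniform for the
#' autoregressive model.
#'
#' @param video an `aligned_pose_video` (see [extract_poses()]).
#' @param n_components number of components D (default 10).
#' @return a [pose_series()] with source `"pca"`, an orthonormal `basis`
#'   (D x pixels) and `explained_variance` fractions.
#' @export
fit_pca <- function(video, n_components = 10) {
  X <- flatten_crops(video)
  valid <- video$valid
  if (sum(valid) <= n_components)
    abort(sprintf("need more than %d valid frames to fit %d components",
                  n_components, n_components))
  pc <- prcomp(X[valid, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  ctr <- sweep(X, 2, pc$center)
  scores <- ctr %*% pc$rotation[, seq_len(k), drop = FALSE]
  scores <- interp_invalid(scores, valid)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  pose_series(scores, fps = video$fps, source = "pca",
              basis = t(pc$rotation[, seq_len(k), drop = FALSE]),
              explained_variance = ev[seq_len(k)])
}

#' Random-projection compression of aligned pose video
#'
#' Multiplies each frame's pixel vector by a seeded Gaussian matrix with
#' entries of variance `1/n_components`, which approximately preserves
#' squared norms (Johnson-Lindenstrauss). Cheaper than PCA and useful for
#' visualizing block structure in the raw data.
#'
#' @param video an `aligned_pose_video`.
#' @param n_components output dimension.
#' @param seed RNG seed for the projection matrix.
#' @return a [pose_series()] with source `"random_projection"`; `basis`
#'   holds the projection rows.
#' @export
random_projection <- function(video, n_components, seed = 1) {
  if (n_components < 1) abort("`n_components` must be >= 1")
  X <- flatten_crops(video)
  set.seed(seed)
  P <- matrix(rnorm(n_components * ncol(X), sd = 1 / sqrt(n_components)),
              n_components, ncol(X))
  pose_series(X %*% t(P), fps = video$fps, source = "random_projection",
              basis = P)
}
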