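#' Estimate the static background of a depth recording
#'
#' Per-pixel median over an evenly spaced sample of frames. With an animal
#' occupying any given pixel in a minority of frames, the median recovers
#' the floor depth there.
#'
#' @param recording a [depth_recording()].
#' @param n_frames number of frames to sample (must not exceed the number
#'   of frames in the recording).
#' @return H x W matrix of background depths (mm).
#' @export
estimate_background <- function(recording, n_frames = 30) {
  T_ <- dim(recording$frames)[1]
  if (T_ == 0) abort("cannot estimate a background from an empty recording")
  if (n_frames > T_)
    abort(sprintf("`n_frames` (%d) exceeds recording length (%d)",
                  n_frames, T_))
  idx <- unique(round(seq(1, T_, length.out = n_frames)))
  sub <- recording$frames[idx, , , drop = FALSE]
  apply(sub, c(2, 3), median)
}

#' Segment the animal in one depth frame
#'
#' Forms the height image `background - frame`, thresholds at
#' `min_height_mm`, and keeps the largest 8-connected component provided
#' its area reaches `min_area_px`; otherwise returns an empty mask (a valid
#' "animal absent" outcome).
#'
#' @param frame H x W depth frame (mm).
#' @param background H x W background depth (mm).
#' @param min_height_mm height threshold above the floor.
#' @param min_area_px minimum component area in pixels.
#' @return H x W logical mask.
#' @export
segment_animal <- function(frame, background, min_height_mm = 10,
                           min_area_px = 50) {
  if (!all(dim(frame) == dim(background)))
    abort("`frame` and `background` shapes differ")
  fg <- (background - frame) >= min_height_mm
  if (!any(fg)) return(fg)
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_px)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab == best
}

# Bilinear sample of img (matrix, rows = y, cols = x) at continuous
# coordinates with pixel centers at (col - 0.5, row - 0.5); outside -> 0.
sample_bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  cx <- x - 0.5; cy <- y - 0.5      # 0-based pixel-center coords
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  get <- function(r, c) {
    ok <- r >= 0 & r < H & c >= 0 & c < W
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok] + 1L, c[ok] + 1L)]
    out
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

circ_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  ifelse(d == -pi, pi, d)
}

#' Egocentric alignment of one segmented frame
#'
#' Computes the animal's centroid (mask center of mass) and heading (the
#' mask's second-moment major axis), resolves the 180-degree axis ambiguity
#' against `prev_heading` if given, otherwise by calling the half of the
#' mask with greater mean height the anterior end, and resamples the height
#' image into a heading-normalized crop (anterior toward +x) centered on
#' the centroid.
#'
#' A circularly symmetric mask has no defined axis; the convention is
#' heading 0 before disambiguation.
#'
#' @param height H x W height-above-floor image (mm); compute as
#'   `pmax(background - frame, 0)`.
#' @param mask H x W logical animal mask (see [segment_animal()]).
#' @param crop_size integer (h, w) of the output crop.
#' @param prev_heading previous frame's heading in radians, or `NULL`.
#' @return list with `crop` (h x w mm, zeros if invalid), `centroid_xy`
#'   (length-2, pixels), `heading` (radians in (-pi, pi]), `valid`.
#' @export
align_egocentric <- function(height, mask, crop_size = c(48, 48),
                             prev_heading = NULL) {
  h <- crop_size[1]; w <- crop_size[2]
  if (!any(mask)) {
    return(list(crop = matrix(0, h, w), centroid_xy = c(NA_real_, NA_real_),
                heading = NA_real_, valid = FALSE))
  }
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 0.5; ys <- idx[, 1] - 0.5
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  hv <- height[mask]
  pick_by_height <- function(th) {
    proj <- dx * cos(th) + dy * sin(th)
    fwd <- proj > 0
    if (!any(fwd) || all(fwd)) return(th)
    if (mean(hv[fwd]) >= mean(hv[!fwd])) th else wrap_angle(th + pi)
  }
  if (!is.null(prev_heading) && is.finite(prev_heading)) {
    cand <- c(theta, theta + pi)
    theta <- cand[which.min(abs(circ_diff(cand, prev_heading)))]
  } else {
    theta <- pick_by_height(theta)
  }
  theta <- wrap_angle(theta)
  # resample: crop pixel (i, j) at offset (u, v) from the crop center maps
  # to arena point centroid + R(theta) (u, v)
  us <- (seq_len(w) - 0.5) - w / 2
  vs <- (seq_len(h) - 0.5) - h / 2
  U <- matrix(us, h, w, byrow = TRUE)
  V <- matrix(vs, h, w)
  sx <- cx + cos(theta) * U - sin(theta) * V
  sy <- cy + sin(theta) * U + cos(theta) * V
  crop <- matrix(sample_bilinear(height, as.numeric(sx), as.numeric(sy)),
                 h, w)
  list(crop = crop, centroid_xy = c(cx, cy), heading = theta, valid = TRUE)
}

#' Spine height profile of an aligned crop
#'
#' Heights sampled at `n_points` evenly spaced stations along the
#' anterior-posterior midline of a heading-normalized crop; each station
#' reports the maximum height within its transverse slice of the animal
#' mask. The block structure of this profile over time is one of the
#' clearest visual signatures of sub-second behavioral modularity.
#'
#' @param crop h x w aligned height crop (mm); zero outside the animal.
#' @param n_points number of stations (>= 2).
#' @return numeric vector of `n_points` heights (mm); all zero when the
#'   crop holds no animal.
#' @export
spine_height_profile <- function(crop, n_points = 20) {
  if (n_points < 2) abort("`n_points` must be >= 2")
  mask_cols <- which(colSums(crop > 0) > 0)
  if (length(mask_cols) == 0) return(numeric(n_points))
  c1 <- min(mask_cols); c2 <- max(mask_cols)
  edges <- seq(c1 - 0.5, c2 + 0.5, length.out = n_points + 1)
  vapply(seq_len(n_points), function(i) {
    cols <- which(seq_len(ncol(crop)) - 0.5 >= edges[i] - 1e-9 &
                    seq_len(ncol(crop)) - 0.5 < edges[i + 1] + 1e-9)
    cols <- intersect(cols, mask_cols[1]:mask_cols[length(mask_cols)])
    if (length(cols) == 0) 0 else max(crop[, cols])
  }, numeric(1))
}

#' Extract aligned pose video from a depth recording
#'
#' Runs background estimation, per-frame segmentation and egocentric
#' alignment over a recording, chaining heading history for the 180-degree
#' disambiguation. Frames where no animal is found are retained with
#' `valid = FALSE` and an all-zero crop.
#'
#' @param recording a [depth_recording()].
#' @param crop_size (h, w) of the aligned crops.
#' @param min_height_mm,min_area_px segmentation parameters.
#' @param n_bg_frames frames sampled for the background median.
#' @param background optional precomputed background.
#' @return An `aligned_pose_video`: crops (T x h x w mm), `centroid_xy`
#'   (T x 2 px), `heading` (T radians), `valid` (T logical), plus fps and
#'   pixel pitch.
#' @export
extract_poses <- function(recording, crop_size = c(48, 48),
                          min_height_mm = 10, min_area_px = 50,
                          n_bg_frames = 30, background = NULL) {
  T_ <- dim(recording$frames)[1]
  if (is.null(background))
    background <- estimate_background(recording,
                                      min(n_bg_frames, max(T_, 1)))
  crops <- array(0, c(T_, crop_size[1], crop_size[2]))
  centroid <- matrix(NA_real_, T_, 2)
  heading <- rep(NA_real_, T_)
  valid <- logical(T_)
  prev <- NULL
  for (t in seq_len(T_)) {
    fr <- recording$frames[t, , ]
    mask <- segment_animal(fr, background, min_height_mm, min_area_px)
    hgt <- pmax(background - fr, 0)
    al <- align_egocentric(hgt, mask, crop_size, prev_heading = prev)
    crops[t, , ] <- al$crop
    centroid[t, ] <- al$centroid_xy
    heading[t] <- al$heading
    valid[t] <- al$valid
    if (al$valid) prev <- al$heading
  }
  structure(list(crops = crops, centroid_xy = centroid, heading = heading,
                 valid = valid, fps = recording$fps,
                 mm_per_px = recording$mm_per_px),
            class = "aligned_pose_video")
}

#' @export
print.aligned_pose_video <- function(x, ...) {
  d <- dim(x$crops)
  cat(sprintf("<aligned_pose_video> %d frames of %dx%d px crops, %d valid\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' @rdname extract_poses
#' @param x an `aligned_pose_video`.
#' @param ... unused.
#' @export
as_tibble.aligned_pose_video <- function(x, ...) {
  tibble(frame = seq_along(x$valid),
         x_px = x$centroid_xy[, 1], y_px = x$centroid_xy[, 2],
         heading_rad = x$heading, valid = x$valid)
}
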