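#' Overhead depth recording
#'
#' A stack of depth frames in millimetres as seen by an overhead camera:
#' larger values are farther from the camera, so the animal appears as a
#' local depth minimum against the arena floor.
#'
#' @param frames numeric array T x H x W of depths (mm), or a H x W matrix
#'   for a single frame.
#' @param fps frames per second (camera default 30).
#' @param floor_depth_mm scalar background (floor) depth.
#' @param mm_per_px pixel pitch on the floor plane.
#' @return An object of class `depth_recording`.
#' @export
depth_recording <- function(frames, fps = 30, floor_depth_mm, mm_per_px = 1) {
  if (is.matrix(frames)) frames <- array(frames, c(1, dim(frames)))
  if (length(dim(frames)) != 3) abort("`frames` must be T x H x W")
  if (any(!is.finite(frames)) || any(frames < 0))
    abort("depths must be finite and non-negative")
  if (fps <= 0) abort("`fps` must be positive")
  structure(list(frames = frames, fps = fps,
                 floor_depth_mm = floor_depth_mm, mm_per_px = mm_per_px),
            class = "depth_recording")
}

#' @export
print.depth_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<depth_recording> %d frames of %dx%d px, %g fps, floor %g mm\n",
              d[1], d[2], d[3], x$fps, x$floor_depth_mm))
  invisible(x)
}

#' @export
dim.depth_recording <- function(x) dim(x$frames)

# Height of the simulated animal above the floor at offsets (u, v) from its
# centroid, u along the heading. Dorsal surface is a half-ellipsoid whose
# posterior half is scaled down so the anterior half is reliably taller —
# the cue the extraction stage uses to resolve the 180-degree heading
# ambiguity. The footprint stays the centered ellipse, so the ground-truth
# centroid matches the mask centroid.
ellipsoid_height <- function(u, v, body_length, body_height,
                             width_frac = 0.45, posterior_drop = 0.2) {
  a <- body_length / 2
  c_ <- a * width_frac
  core <- 1 - (u / a)^2 - (v / c_)^2
  h <- body_height * sqrt(pmax(core, 0))
  taper <- 1 - posterior_drop * pmax(-u, 0) / a
  h * taper
}

#' Render a depth video of a simulated animal
#'
#' Each frame is the arena floor depth minus an ellipsoidal height bump
#' centered at the track's centroid with its major axis along the heading;
#' the posterior half is slightly lower than the anterior half so heading is
#' recoverable from shape alone. Optional per-pixel Gaussian sensor noise.
#'
#' @param track data frame with one row per frame: columns `x_mm`, `y_mm`
#'   (centroid; x is rightward along image columns, y downward along rows),
#'   `heading_rad` (from +x, positive toward +y), and optionally
#'   `body_length_mm`, `body_height_mm` (recycled defaults 60 and 35).
#' @param arena list with `h_px`, `w_px`, `floor_depth_mm`, and optionally
#'   `mm_per_px` (default 1).
#' @param noise_sd_mm per-pixel sensor noise standard deviation (default 0).
#' @param seed RNG seed for the sensor noise.
#' @param fps frame rate recorded in the output.
#' @return a [depth_recording()]; zero-length tracks give a 0-frame
#'   recording.
#' @export
render_depth_video <- function(track, arena, noise_sd_mm = 0, seed = 1,
                               fps = 30) {
  h_px <- arena$h_px; w_px <- arena$w_px
  mm_per_px <- arena$mm_per_px %||% 1
  floor_mm <- arena$floor_depth_mm
  n <- nrow(track)
  if (is.null(n) || n == 0)
    return(depth_recording(array(floor_mm, c(0, h_px, w_px)), fps = fps,
                           floor_depth_mm = floor_mm, mm_per_px = mm_per_px))
  if (!all(c("x_mm", "y_mm", "heading_rad") %in% names(track)))
    abort("`track` needs columns x_mm, y_mm, heading_rad")
  body_length <- track[["body_length_mm"]] %||% rep(60, n)
  body_height <- track[["body_height_mm"]] %||% rep(35, n)
  if (length(body_length) == 1) body_length <- rep(body_length, n)
  if (length(body_height) == 1) body_height <- rep(body_height, n)
  if (any(body_length <= 0) || any(body_height <= 0))
    abort("body dimensions must be positive")
  xmax <- w_px * mm_per_px; ymax <- h_px * mm_per_px
  oob <- track$x_mm < 0 | track$x_mm > xmax | track$y_mm < 0 |
    track$y_mm > ymax
  if (any(oob))
    abort(sprintf("track leaves the arena at frame %d", which(oob)[1]))
  set.seed(seed)
  # pixel-center coordinates in mm
  xs <- (seq_len(w_px) - 0.5) * mm_per_px
  ys <- (seq_len(h_px) - 0.5) * mm_per_px
  px <- matrix(xs, h_px, w_px, byrow = TRUE)
  py <- matrix(ys, h_px, w_px)
  frames <- array(0, c(n, h_px, w_px))
  for (t in seq_len(n)) {
    dx <- px - track$x_mm[t]
    dy <- py - track$y_mm[t]
    th <- track$heading_rad[t]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    hgt <- ellipsoid_height(u, v, body_length[t], body_height[t])
    fr <- floor_mm - hgt
    if (noise_sd_mm > 0)
      fr <- fr + matrix(rnorm(h_px * w_px, sd = noise_sd_mm), h_px, w_px)
    frames[t, , ] <- pmax(fr, 0)
  }
  depth_recording(frames, fps = fps, floor_depth_mm = floor_mm,
                  mm_per_px = mm_per_px)
}

#' Simulate a smooth exploration track
#'
#' A slowly turning constant-speed walk with reflecting walls, for
#' end-to-end tests of the measurement pipeline.
#'
#' @param n_frames number of frames.
#' @param arena arena list as in [render_depth_video()].
#' @param seed RNG seed.
#' @param speed_mm speed per frame.
#' @param turn_sd_rad per-frame heading increment standard deviation.
#' @param margin_mm wall margin the centroid keeps.
#' @param body_length_mm,body_height_mm body dimensions written to the track.
#' @return tibble with columns `frame`, `x_mm`, `y_mm`, `heading_rad`,
#'   `body_length_mm`, `body_height_mm`.
#' @export
simulate_track <- function(n_frames, arena, seed = 1, speed_mm = 2,
                           turn_sd_rad = 0.08, margin_mm = 40,
                           body_length_mm = 60, body_height_mm = 35) {
  set.seed(seed)
  mm_per_px <- arena$mm_per_px %||% 1
  xmax <- arena$w_px * mm_per_px; ymax <- arena$h_px * mm_per_px
  x <- numeric(n_frames); y <- numeric(n_frames); th <- numeric(n_frames)
  x[1] <- xmax / 2; y[1] <- ymax / 2; th[1] <- runif(1, -pi, pi)
  max_turn <- 0.3   # physical cap on per-frame body rotation (rad)
  for (t in seq_len(n_frames - 1)) {
    turn <- rnorm(1, sd = turn_sd_rad)
    # steer smoothly back toward the center near walls
    if (x[t] < margin_mm || x[t] > xmax - margin_mm ||
        y[t] < margin_mm || y[t] > ymax - margin_mm) {
      to_center <- atan2(ymax / 2 - y[t], xmax / 2 - x[t])
      d <- circ_diff(to_center, th[t])
      turn <- turn + sign(d) * min(abs(d), max_turn)
    }
    th[t + 1] <- th[t] + max(min(turn, max_turn), -max_turn)
    x[t + 1] <- min(max(x[t] + speed_mm * cos(th[t + 1]), margin_mm / 2),
                    xmax - margin_mm / 2)
    y[t + 1] <- min(max(y[t] + speed_mm * sin(th[t + 1]), margin_mm / 2),
                    ymax - margin_mm / 2)
  }
  tibble(frame = seq_len(n_frames), x_mm = x, y_mm = y,
         heading_rad = wrap_angle(th),
         body_length_mm = body_length_mm, body_height_mm = body_height_mm)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
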