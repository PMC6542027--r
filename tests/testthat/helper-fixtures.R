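# Small fixed models and arenas used across tests.

# Two-state scalar AR(1) model with hand-picked, well-conditioned values.
tiny_two_state_model <- function() {
  arhmm_model(
    A = list(matrix(0.8, 1, 1), matrix(-0.5, 1, 1)),
    b = matrix(c(0.3, -0.2), 1, 2),
    Sigma = array(c(0.5, 0.8), c(1, 1, 2)),
    pi = matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE),
    beta = c(0.5, 0.5), ar_lag = 1)
}

test_arena <- function(h = 160, w = 160, floor = 650)
  list(h_px = h, w_px = w, floor_depth_mm = floor)

flat_background <- function(arena)
  matrix(arena$floor_depth_mm, arena$h_px, arena$w_px)

# Render a single stationary animal frame at a given heading.
render_one <- function(heading, arena = test_arena(), x = NULL, y = NULL,
                       body_length = 60, body_height = 35,
                       noise_sd = 0, seed = 1) {
  track <- tibble::tibble(
    frame = 1,
    x_mm = x %||% (arena$w_px / 2), y_mm = y %||% (arena$h_px / 2),
    heading_rad = heading,
    body_length_mm = body_length, body_height_mm = body_height)
  render_depth_video(track, arena, noise_sd_mm = noise_sd, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Optimal injective matching of true to estimated labels; returns the
# fraction of frames that agree under the best assignment.
match_accuracy <- function(true, est) {
  tt <- sort(unique(true)); ee <- sort(unique(est))
  C <- as.matrix(table(factor(true, tt), factor(est, ee)))
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > length(tt)) { best <<- max(best, acc); return(invisible()) }
    # bound: remaining rows can add at most their row maxima
    bound <- acc + sum(apply(C[i:length(tt), setdiff(seq_along(ee), used),
                               drop = FALSE], 1, max))
    if (bound <= best) return(invisible())
    for (j in order(-C[i, ])) {
      if (j %in% used) next
      recurse(i + 1, c(used, j), acc + C[i, j])
    }
  }
  recurse(1, integer(), 0)
  best / length(true)
}

# Simple CUSUM change-point count on a multivariate series: flags a change
# when the cumulative deviation of the norm trace from its running mean
# exceeds `thresh` standard deviations (threshold calibrated on white noise
# by the caller).
cusum_changepoints <- function(X, thresh) {
  v <- sqrt(rowSums(X^2))
  v <- diff(v)                 # near-stationary increments
  mu <- mean(v); sdv <- sd(v)
  pos <- 0; neg <- 0; count <- 0
  for (x in (v - mu) / sdv) {
    pos <- max(0, pos + x - 0.5)
    neg <- min(0, neg + x + 0.5)
    if (pos > thresh || -neg > thresh) {
      count <- count + 1
      pos <- 0; neg <- 0
    }
  }
  count
}

# Dense multivariate-normal log density via direct inversion (independent
# of the package's cholesky-backsolve path).
dense_mvn_logpdf <- function(x, mu, Sigma) {
  D <- length(mu)
  r <- x - mu
  as.numeric(
    -0.5 * (D * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
              as.numeric(t(r) %*% solve(Sigma) %*% r)))
}
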