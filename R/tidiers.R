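#' Tidy a fitted syllable model
#'
#' One row per used syllable: usage, instance count, mean duration, and
#' the noise magnitude of its AR regime.
#'
#' @param x an `arhmm_fit` from [fit_arhmm()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.arhmm_fit <- function(x, ...) {
  u <- usages(x$labels)
  d <- durations(x$labels)
  dsum <- dplyr::summarise(dplyr::group_by(d, .data$syllable),
                           n_instances = dplyr::n(),
                           mean_duration_s = mean(.data$duration_s),
                           .groups = "drop")
  out <- dplyr::left_join(u, dsum, by = "syllable")
  out$noise_sd <- vapply(out$syllable, function(k)
    sqrt(mean(diag(matrix(x$model$Sigma[, , k], x$model$D, x$model$D)))),
    numeric(1))
  dplyr::arrange(out, dplyr::desc(.data$usage))
}

#' Glance at a fitted syllable model
#'
#' @param x an `arhmm_fit`.
#' @param ... unused.
#' @return a one-row tibble: frames, used states, truncation, final joint
#'   log probability, grand mean syllable duration.
#' @export
glance.arhmm_fit <- function(x, ...) {
  d <- durations(x$labels)
  tibble(n_frames = x$labels$T,
         n_used_states = length(unique(x$labels$labels)),
         K_max = x$model$K_max,
         ar_lag = x$model$ar_lag,
         kappa = x$model$hdp$kappa,
         joint_logprob = tail(x$diagnostics$joint_logprob, 1),
         mean_duration_s = mean(d$duration_s),
         n_sweeps = x$config$n_sweeps)
}

#' Plot a pose series as stacked component traces
#'
#' @param object a [pose_series()].
#' @param max_frames cap on frames drawn.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pose_series <- function(object, max_frames = 3000, ...) {
  d <- as_tibble(object)
  d <- d[seq_len(min(nrow(d), max_frames)), ]
  long <- tidyr::pivot_longer(d, dplyr::starts_with("pc"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("pose series (%s)", object$source)) +
    ggplot2::theme_minimal()
}

#' Plot a behavioral state map
#'
#' Nodes sized by usage, edges weighted by transition probability —
#' the standard graph rendering of an experiment's behavioral repertoire.
#'
#' @param object a `state_map` from [build_state_map()].
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.state_map <- function(object, seed = 1, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges, directed = TRUE,
    vertices = data.frame(name = as.character(object$nodes$syllable),
                          usage = object$nodes$usage))
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(syllable = object$nodes$syllable,
                  usage = object$nodes$usage,
                  x = lay[, 1], y = lay[, 2])
  ed <- dplyr::left_join(object$edges,
                         dplyr::select(nodes, "syllable", xf = "x", yf = "y"),
                         by = c(from = "syllable"))
  ed <- dplyr::left_join(ed,
                         dplyr::select(nodes, "syllable", xt = "x", yt = "y"),
                         by = c(to = "syllable"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$xf, y = .data$yf, xend = .data$xt,
                   yend = .data$yt, linewidth = .data$p),
      alpha = 0.4, color = "grey40") +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$usage),
      color = "steelblue") +
    ggplot2::geom_text(data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$syllable), vjust = -1) +
    ggplot2::scale_linewidth(range = c(0.1, 1.5)) +
    ggplot2::labs(title = "behavioral state map",
                  size = "usage", linewidth = "transition p") +
    ggplot2::theme_void()
}

#' Plot a two-condition usage comparison
#'
#' Per-syllable usage change with significance marks, the standard
#' condition-versus-control syllable plot.
#'
#' @param object a [compare_usages()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.usage_comparison <- function(object, ...) {
  d <- as_tibble(object)
  d$syllable <- factor(d$syllable)
  ggplot2::ggplot(d, ggplot2::aes(.data$syllable, .data$effect,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = d[d$significant, , drop = FALSE],
                       ggplot2::aes(label = "*"), vjust = -0.2, size = 6) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "syllable", y = "usage difference (B - A)",
                  title = "syllable usage change between conditions") +
    ggplot2::theme_minimal()
}

#' Plot fit diagnostics
#'
#' Per-sweep joint log probability and used-state count.
#'
#' @param object an `arhmm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.arhmm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$diagnostics, -"sweep",
                              names_to = "diagnostic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sweep, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$diagnostic, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Gibbs sweep", y = NULL) +
    ggplot2::theme_minimal()
}
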