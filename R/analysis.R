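# Run-length encoding of a label vector -> tibble(state, length, start).
label_runs <- function(z) {
  r <- rle(as.integer(z))
  tibble(state = r$values, length = r$lengths,
         start = cumsum(c(1L, r$lengths[-length(r$lengths)])))
}

#' Syllable usages
#'
#' Fraction of an experiment each syllable accounts for, either by frames
#' (fraction of frames carrying the label) or by instances (fraction of
#' runs — maximal constant blocks — belonging to the syllable). Usages sum
#' to 1.
#'
#' @param labels a [label_sequence()], a data frame with a `state` column,
#'   or an integer vector.
#' @param mode `"frames"` (default) or `"instances"`.
#' @return tibble with columns `syllable`, `usage`.
#' @export
usages <- function(labels, mode = c("frames", "instances")) {
  mode <- match.arg(mode)
  z <- as_label_vector(labels)
  if (length(z) == 0) abort("`labels` is empty")
  runs <- label_runs(z)
  d <- if (mode == "frames") {
    dplyr::summarise(dplyr::group_by(runs, syllable = .data$state),
                     usage = sum(.data$length) / length(z), .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(runs, syllable = .data$state),
                     usage = dplyr::n() / nrow(runs), .groups = "drop")
  }
  dplyr::arrange(d, .data$syllable)
}

#' Syllable duration samples
#'
#' Run-length encodes the labels; each run contributes `length / fps`
#' seconds to its syllable's duration sample. On real mouse recordings the
#' grand mean of these durations sits around 300 ms.
#'
#' @param labels a [label_sequence()], data frame, or vector.
#' @param fps frames per second (taken from the label_sequence if given).
#' @return tibble with columns `syllable`, `duration_s`, one row per run.
#' @export
durations <- function(labels, fps = NULL) {
  fps <- labels_fps(labels, fps)
  z <- as_label_vector(labels)
  runs <- label_runs(z)
  tibble(syllable = runs$state, duration_s = runs$length / fps)
}

#' Syllable-to-syllable transition matrix
#'
#' Transitions are counted between consecutive runs of the run-length
#' encoded sequence, so self-transitions are structurally absent (the
#' sticky model's dwell handling would otherwise dominate every edge);
#' rows are normalized to probabilities. Syllables with no outgoing
#' transitions are flagged terminal.
#'
#' @param labels a [label_sequence()], data frame, or vector with at least
#'   two runs.
#' @param exclude_self kept for the interface; run encoding already removes
#'   self-pairs. Must be `TRUE`.
#' @return square row-stochastic matrix over used syllables (dimnames are
#'   syllable IDs) with attributes `counts` and `terminal`.
#' @export
transition_matrix <- function(labels, exclude_self = TRUE) {
  if (!isTRUE(exclude_self))
    abort("run-encoded transitions have no self-pairs; exclude_self must be TRUE")
  z <- as_label_vector(labels)
  runs <- label_runs(z)$state
  sylls <- sort(unique(z))
  K <- length(sylls)
  counts <- matrix(0, K, K, dimnames = list(sylls, sylls))
  if (length(runs) >= 2) {
    from <- match(runs[-length(runs)], sylls)
    to <- match(runs[-1], sylls)
    counts <- matrix(tabulate((to - 1L) * K + from, nbins = K * K), K, K,
                     dimnames = list(sylls, sylls))
  }
  rs <- rowSums(counts)
  terminal <- rs == 0
  P <- counts
  P[!terminal, ] <- counts[!terminal, , drop = FALSE] / rs[!terminal]
  attr(P, "counts") <- counts
  attr(P, "terminal") <- terminal
  P
}

#' Build a behavioral state map
#'
#' The graph summary of an experiment's behavior: nodes are syllables
#' weighted by usage, directed edges are observed transitions weighted by
#' probability. Nodes below `min_usage` and edges below `min_edge_p` are
#' dropped and the retained usages renormalized.
#'
#' @param usage tibble from [usages()].
#' @param transitions matrix from [transition_matrix()].
#' @param min_usage minimum usage for a node to be kept.
#' @param min_edge_p minimum transition probability for an edge.
#' @return An object of class `state_map`: `nodes` (tibble syllable,
#'   usage), `edges` (tibble from, to, p), `usage_mode`, thresholds.
#'   An empty graph after thresholding is returned with a warning.
#' @export
build_state_map <- function(usage, transitions, min_usage = 0,
                            min_edge_p = 0) {
  mode <- attr(usage, "usage_mode") %||% "frames"
  keep <- usage$usage >= min_usage
  nodes <- usage[keep, , drop = FALSE]
  if (nrow(nodes) == 0) {
    warn("state map is empty after usage thresholding")
    return(structure(list(nodes = tibble(syllable = integer(),
                                         usage = numeric()),
                          edges = tibble(from = integer(), to = integer(),
                                         p = numeric()),
                          usage_mode = mode, min_usage = min_usage,
                          min_edge_p = min_edge_p),
                     class = "state_map"))
  }
  nodes$usage <- nodes$usage / sum(nodes$usage)
  sylls <- as.integer(rownames(transitions))
  edges <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(transitions, .name_repair = ~ as.character(sylls)),
                  from = sylls),
    -"from", names_to = "to", values_to = "p")
  edges$to <- as.integer(edges$to)
  edges <- dplyr::filter(edges, .data$p > 0, .data$p >= min_edge_p,
                         .data$from %in% nodes$syllable,
                         .data$to %in% nodes$syllable)
  structure(list(nodes = nodes, edges = edges[order(edges$from, edges$to), ],
                 usage_mode = mode, min_usage = min_usage,
                 min_edge_p = min_edge_p),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat(sprintf("<state_map> %d syllables, %d edges (usage mode: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$usage_mode))
  invisible(x)
}

#' Compare syllable usages between two conditions
#'
#' Per-syllable statistic: difference in mean per-session usage (condition
#' B minus A). The null is built by permuting session-to-condition
#' assignments — sessions, not frames, are the exchangeable replicates —
#' giving two-sided p-values, then Benjamini-Hochberg q-values at level
#' `fdr`.
#'
#' @param labels_a,labels_b lists of per-session labels (each element a
#'   [label_sequence()], data frame, or vector); at least 2 sessions per
#'   condition.
#' @param n_permutations number of permutations.
#' @param fdr false-discovery-rate level for the `significant` flag.
#' @param seed RNG seed.
#' @param mode usage mode passed to [usages()].
#' @return An object of class `usage_comparison`: a tibble with per-syllable
#'   `usage_a`, `usage_b`, `effect`, `p_value`, `q_value`, `significant`,
#'   plus attributes `n_permutations`, `fdr`, `seed`.
#' @export
compare_usages <- function(labels_a, labels_b, n_permutations = 1000,
                           fdr = 0.05, seed = 1, mode = "frames") {
  if (length(labels_a) < 2 || length(labels_b) < 2)
    abort(paste("a permutation null needs at least 2 sessions per condition;",
                "got", length(labels_a), "and", length(labels_b)))
  set.seed(seed)
  usage_list <- function(ll) lapply(ll, usages, mode = mode)
  ua <- usage_list(labels_a); ub <- usage_list(labels_b)
  sylls <- sort(unique(unlist(lapply(c(ua, ub), `[[`, "syllable"))))
  mat <- function(ul) t(vapply(ul, function(u) {
    v <- setNames(rep(0, length(sylls)), sylls)
    v[as.character(u$syllable)] <- u$usage
    v
  }, numeric(length(sylls))))
  Ma <- mat(ua); Mb <- mat(ub)
  na <- nrow(Ma); nb <- nrow(Mb)
  M <- rbind(Ma, Mb)
  obs <- colMeans(Mb) - colMeans(Ma)
  perm_stats <- matrix(0, n_permutations, length(sylls))
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(na + nb)
    grp_b <- idx > na
    perm_stats[i, ] <- colMeans(M[grp_b, , drop = FALSE]) -
      colMeans(M[!grp_b, , drop = FALSE])
  }
  p <- vapply(seq_along(sylls), function(j)
    (1 + sum(abs(perm_stats[, j]) >= abs(obs[j]) - 1e-12)) /
      (n_permutations + 1), numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- tibble(syllable = sylls,
                usage_a = colMeans(Ma), usage_b = colMeans(Mb),
                effect = obs, p_value = p, q_value = q,
                significant = q < fdr)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "fdr") <- fdr
  attr(out, "seed") <- seed
  class(out) <- c("usage_comparison", class(out))
  out
}

#' Difference between two state maps
#'
#' Edgewise `p_B - p_A` over the union of edges (an edge absent from one
#' map contributes 0); positive deltas are upregulated in condition B,
#' negative downregulated. Edges with |delta| below `min_abs_delta` are
#' dropped.
#'
#' @param map_a,map_b [build_state_map()] outputs built with identical
#'   thresholds and usage mode.
#' @param min_abs_delta minimum absolute change to keep an edge.
#' @return tibble with columns `from`, `to`, `delta`.
#' @export
difference_state_map <- function(map_a, map_b, min_abs_delta = 0) {
  if (!identical(map_a$usage_mode, map_b$usage_mode))
    abort("state maps were built with different usage modes")
  if (!isTRUE(all.equal(c(map_a$min_usage, map_a$min_edge_p),
                        c(map_b$min_usage, map_b$min_edge_p))))
    abort("state maps were built with different thresholds")
  ea <- dplyr::rename(map_a$edges, p_a = "p")
  eb <- dplyr::rename(map_b$edges, p_b = "p")
  j <- dplyr::full_join(ea, eb, by = c("from", "to"))
  j <- dplyr::mutate(j,
    delta = dplyr::coalesce(.data$p_b, 0) - dplyr::coalesce(.data$p_a, 0))
  out <- dplyr::filter(j, abs(.data$delta) >= min_abs_delta,
                       abs(.data$delta) > 0)
  dplyr::arrange(dplyr::select(out, "from", "to", "delta"),
                 .data$from, .data$to)
}
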