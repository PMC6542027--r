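# Atomic write: produce the file under a temp name in the same directory,
# then rename into place.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path),
                  fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# CSV with "# key: value" metadata comment lines ahead of the header.
write_csv_meta <- function(df, path, meta = list()) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)),
                 con)
    writeLines(readr::format_csv(df), con, sep = "")
  })
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  df <- readr::read_csv(I(lines[!startsWith(lines, "# ")]),
                        show_col_types = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write / read a depth recording as a 16-bit TIFF frame directory
#'
#' Frames are rounded to whole millimetres and stored as 16-bit grayscale
#' TIFFs (`frame_00001.tif`, ...) beside a `meta.yaml` carrying `fps`,
#' `floor_depth_mm`, `mm_per_px` and the frame count. The roundtrip is
#' lossless at 1 mm quantization.
#'
#' @param recording a [depth_recording()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (writer); a [depth_recording()] (reader).
#' @export
write_depth_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T_ <- dim(recording$frames)[1]
  for (t in seq_len(T_)) {
    fr <- round(recording$frames[t, , ])
    fr <- pmin(pmax(fr, 0), 65535)
    path <- file.path(dir, sprintf("frame_%05d.tif", t))
    write_atomic(path, function(tmp)
      tiff::writeTIFF(fr / 65535, tmp, bits.per.sample = 16))
  }
  meta <- list(fps = recording$fps,
               floor_depth_mm = recording$floor_depth_mm,
               mm_per_px = recording$mm_per_px, n_frames = T_)
  write_atomic(file.path(dir, "meta.yaml"), function(tmp)
    yaml::write_yaml(meta, tmp))
  invisible(dir)
}

#' @rdname write_depth_recording
#' @export
read_depth_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path))
    abort(sprintf("not a depth recording directory (missing %s)", meta_path))
  meta <- yaml::read_yaml(meta_path)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) != meta$n_frames)
    abort(sprintf("expected %d frames in %s, found %d",
                  meta$n_frames, dir, length(files)))
  if (length(files) == 0) {
    frames <- array(0, c(0, 1, 1))
  } else {
    f1 <- tiff::readTIFF(files[1]) * 65535
    frames <- array(0, c(length(files), nrow(f1), ncol(f1)))
    frames[1, , ] <- f1
    for (t in seq_along(files)[-1])
      frames[t, , ] <- tiff::readTIFF(files[t]) * 65535
  }
  depth_recording(round(frames), fps = meta$fps,
                  floor_depth_mm = meta$floor_depth_mm,
                  mm_per_px = meta$mm_per_px)
}

#' Write / read per-frame labels as CSV
#'
#' Columns `frame`, `state`; frame rate and any extra parameters are
#' echoed as `# key: value` comment lines so every output records how it
#' was produced.
#'
#' @param labels a [label_sequence()].
#' @param path CSV path.
#' @param meta named list of extra metadata to echo.
#' @return `path` invisibly (writer); a [label_sequence()] (reader).
#' @export
write_labels_csv <- function(labels, path, meta = list()) {
  meta <- c(list(fps = labels$fps, model_id = labels$model_id), meta)
  write_csv_meta(as_tibble(labels), path, meta)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- read_csv_meta(path)
  meta <- attr(df, "meta")
  fps <- as.numeric(meta$fps %||% 30)
  label_sequence(df$state, fps = fps,
                 model_id = meta$model_id %||% NA_character_)
}

#' Write / read a pose series
#'
#' JSON carries the full object (values, basis, explained variance,
#' attributes) losslessly; [write_pose_series_csv()] exports the values
#' with metadata comments for spreadsheet use.
#'
#' @param series a [pose_series()].
#' @param path output path.
#' @return `path` invisibly (writers); a [pose_series()] (reader).
#' @export
write_pose_series_json <- function(series, path) {
  obj <- list(values = series$values, fps = series$fps,
              source = series$source, basis = series$basis,
              explained_variance = series$explained_variance)
  write_atomic(path, function(tmp)
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE,
                         null = "null", matrix = "rowmajor"))
  invisible(path)
}

#' @rdname write_pose_series_json
#' @export
read_pose_series_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pose_series(obj$values, fps = obj$fps, source = obj$source,
              basis = obj$basis,
              explained_variance = obj$explained_variance)
}

#' @rdname write_pose_series_json
#' @param meta named list echoed as comment lines.
#' @export
write_pose_series_csv <- function(series, path, meta = list()) {
  meta <- c(list(fps = series$fps, source = series$source), meta)
  df <- as_tibble(as.data.frame(series$values,
                                col.names = paste0("pc", seq_len(ncol(series$values)))))
  names(df) <- paste0("pc", seq_len(ncol(df)))
  write_csv_meta(df, path, meta)
  invisible(path)
}

#' @rdname write_pose_series_json
#' @export
read_pose_series_csv <- function(path) {
  df <- read_csv_meta(path)
  meta <- attr(df, "meta")
  pose_series(as.matrix(df), fps = as.numeric(meta$fps %||% 30),
              source = meta$source %||% "synthetic")
}

#' Write / read a fitted model as JSON
#'
#' All per-state parameters, the transition structure and the
#' hyperparameters are serialized at full floating-point precision.
#'
#' @param model an [arhmm_model()].
#' @param path JSON path.
#' @param meta named list of extra fields (seed, sweep counts, ...).
#' @return `path` invisibly (writer); an [arhmm_model()] (reader).
#' @export
write_arhmm_json <- function(model, path, meta = list()) {
  obj <- list(K_max = model$K_max, D = model$D, ar_lag = model$ar_lag,
              A = model$A, b = model$b,
              Sigma = lapply(seq_len(model$K_max), function(k)
                matrix(model$Sigma[, , k], model$D, model$D)),
              pi = model$pi, beta = model$beta, hdp = model$hdp,
              fps = model$fps, meta = meta)
  write_atomic(path, function(tmp)
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor"))
  invisible(path)
}

#' @rdname write_arhmm_json
#' @export
read_arhmm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- o$K_max; D <- o$D
  # a list of equal-shaped matrices may simplify to a K x . x . array
  pick <- function(x, k, nr, nc) {
    if (is.list(x)) matrix(x[[k]], nr, nc)
    else if (length(dim(x)) == 3) matrix(x[k, , ], nr, nc)
    else matrix(x, nr, nc)
  }
  Sigma <- array(0, c(D, D, K))
  for (k in seq_len(K)) Sigma[, , k] <- pick(o$Sigma, k, D, D)
  A <- lapply(seq_len(K), function(k) pick(o$A, k, D, D * o$ar_lag))
  arhmm_model(A = A, b = matrix(o$b, D, K), Sigma = Sigma,
              pi = matrix(o$pi, K, K), beta = o$beta, ar_lag = o$ar_lag,
              gamma = o$hdp$gamma, alpha = o$hdp$alpha, kappa = o$hdp$kappa,
              fps = o$fps)
}

state_map_igraph <- function(map, edge_attr = "p") {
  g <- igraph::graph_from_data_frame(
    map$edges %||% map, directed = TRUE,
    vertices = if (!is.null(map$nodes))
      data.frame(name = as.character(map$nodes$syllable),
                 usage = map$nodes$usage) else NULL)
  g
}

#' Export a state map as GraphML or DOT
#'
#' Nodes carry a `usage` attribute, edges a `p` (transition probability)
#' or `delta` (difference map) attribute, matching how state-map figures
#' size nodes and weight edges.
#'
#' @param map a `state_map` from [build_state_map()], or a difference-map
#'   tibble from [difference_state_map()].
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_state_map <- function(map, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- if (inherits(map, "state_map")) {
    igraph::graph_from_data_frame(
      map$edges, directed = TRUE,
      vertices = data.frame(name = as.character(map$nodes$syllable),
                            usage = map$nodes$usage))
  } else {
    igraph::graph_from_data_frame(map, directed = TRUE)
  }
  write_atomic(path, function(tmp)
    igraph::write_graph(g, tmp, format = format))
  invisible(path)
}

#' Export a usage comparison as CSV
#'
#' @param comparison a [compare_usages()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_usage_comparison_csv <- function(comparison, path) {
  write_csv_meta(as_tibble(comparison), path,
                 meta = list(n_permutations = attr(comparison, "n_permutations"),
                             fdr = attr(comparison, "fdr"),
                             seed = attr(comparison, "seed")))
  invisible(path)
}
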