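# Allowed configuration keys per section; unknown keys are rejected so a
# typo never silently falls back to a default.
config_schema <- list(
  seed = NULL,
  paths = c("out_dir", "depth_dir", "series_csv", "labels_csv", "model_json",
            "labels_csv_a", "labels_csv_b", "test_series_csv"),
  simulate = c("n_states", "dim", "ar_lag", "mean_duration_frames",
               "n_frames", "noise_scale", "separation", "fps", "nonmodular",
               "smoothness", "render", "arena_h_px", "arena_w_px",
               "floor_depth_mm"),
  extract = c("crop_h", "crop_w", "min_height_mm", "min_area_px",
              "n_bg_frames"),
  features = c("method", "n_components"),
  model = c("n_sweeps", "n_burnin", "K_max", "ar_lag",
            "target_mean_duration_s", "gamma", "alpha", "kappa"),
  analysis = c("usage_mode", "fdr", "min_usage", "min_edge_p",
               "n_permutations"),
  evaluate = c("train_fraction", "gmm_components", "fractions")
)

#' Read and validate a pipeline configuration
#'
#' Flat YAML with one section per stage. Every key must be known; unknown
#' keys are an error, not a warning, and the full configuration is echoed
#' into each stage's outputs.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return the validated configuration list, class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) abort("configuration must be a YAML mapping")
  bad_sections <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sections) > 0)
    abort(sprintf("unknown configuration section: %s",
                  paste(bad_sections, collapse = ", ")))
  for (sec in intersect(names(cfg), names(config_schema))) {
    if (sec == "seed") next
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad) > 0)
      abort(sprintf("unknown key in section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

config_flat <- function(cfg) {
  out <- list()
  for (sec in names(cfg)) {
    v <- cfg[[sec]]
    if (is.list(v)) {
      for (k in names(v))
        out[[paste(sec, k, sep = ".")]] <- v[[k]]
    } else out[[sec]] <- v
  }
  out
}

write_run_log <- function(out_dir, stage, cfg, seed, elapsed_s) {
  flat <- config_flat(cfg)
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("syllableseq"))),
    sprintf("seed: %d", seed),
    sprintf("wall_time_s: %.2f", elapsed_s),
    sprintf("config_hash: %s",
            format(sum(utf8ToInt(paste(names(flat),
                                       vapply(flat, paste, "", collapse = ","),
                                       collapse = ";"))), scientific = FALSE)),
    "config:",
    sprintf("  %s: %s", names(flat),
            vapply(flat, function(x) paste(format(x), collapse = ","), ""))
  )
  write_atomic(file.path(out_dir, sprintf("run_%s.log", stage)),
               function(tmp) writeLines(lines, tmp))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic series, optionally rendered to depth
#' video), `extract` (depth video to aligned poses), `features` (aligned
#' poses to pose series), `train` (fit the model), `apply` (label a series
#' with an existing model), `analyze` (labels to usages, durations,
#' transitions, state map), `compare` (two-condition usage comparison),
#' `evaluate` (held-out model comparison and state-count curve). Outputs
#' are written atomically with the configuration echoed into each file;
#' identical inputs, configuration and seed reproduce identical outputs.
#'
#' @param stage stage name.
#' @param config a [read_pipeline_config()] result, a path to one, or a
#'   list.
#' @param out_dir output directory (overrides `paths.out_dir`).
#' @param seed seed (overrides `seed` in the config; default 1).
#' @return (invisibly) a list of the paths written.
#' @export
run_stage <- function(stage = c("simulate", "extract", "features", "train",
                                "apply", "analyze", "compare", "evaluate"),
                      config, out_dir = NULL, seed = NULL) {
  stage <- match.arg(stage)
  cfg <- read_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1)
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    abort("no output directory: set paths.out_dir or `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path))
      abort(sprintf("missing %s input: %s (expected %s)", stage,
                    path %||% "<unset>", what))
    path
  }
  flat <- config_flat(cfg)
  flat$seed <- NULL   # the effective seed is echoed explicitly
  meta <- c(list(stage = stage, seed = seed), flat)
  written <- switch(stage,
    simulate = {
      sc <- cfg$simulate %||% list()
      paths <- list()
      if (isTRUE(sc$nonmodular)) {
        series <- generate_nonmodular_series(
          dim = sc$dim %||% 10, n_frames = sc$n_frames %||% 5000,
          smoothness = sc$smoothness %||% 0.98, seed = seed,
          fps = sc$fps %||% 30)
        paths$series <- file.path(out_dir, "series.csv")
        write_pose_series_csv(series, paths$series, meta)
      } else {
        gen <- generate_arhmm_series(
          n_states = sc$n_states %||% 5, dim = sc$dim %||% 10,
          ar_lag = sc$ar_lag %||% 1,
          mean_duration_frames = sc$mean_duration_frames %||% 9,
          n_frames = sc$n_frames %||% 5000,
          noise_scale = sc$noise_scale %||% 0.1, seed = seed,
          separation = sc$separation %||% 4, fps = sc$fps %||% 30)
        paths$series <- file.path(out_dir, "series.csv")
        paths$true_labels <- file.path(out_dir, "true_labels.csv")
        write_pose_series_csv(gen$series, paths$series, meta)
        write_labels_csv(
          label_sequence(gen$truth$true_labels, fps = gen$series$fps),
          paths$true_labels, meta)
      }
      if (isTRUE(sc$render)) {
        arena <- list(h_px = sc$arena_h_px %||% 192,
                      w_px = sc$arena_w_px %||% 192,
                      floor_depth_mm = sc$floor_depth_mm %||% 650)
        track <- simulate_track(sc$n_frames %||% 300, arena, seed = seed)
        rec <- render_depth_video(track, arena, seed = seed,
                                  fps = sc$fps %||% 30)
        paths$depth_dir <- file.path(out_dir, "depth")
        write_depth_recording(rec, paths$depth_dir)
      }
      paths
    },
    extract = {
      ec <- cfg$extract %||% list()
      rec <- read_depth_recording(need(cfg$paths$depth_dir,
                                       "a depth recording directory"))
      video <- extract_poses(rec,
        crop_size = c(ec$crop_h %||% 48, ec$crop_w %||% 48),
        min_height_mm = ec$min_height_mm %||% 10,
        min_area_px = ec$min_area_px %||% 50,
        n_bg_frames = ec$n_bg_frames %||% 30)
      track_path <- file.path(out_dir, "track.csv")
      write_csv_meta(as_tibble(video), track_path, meta)
      crops_path <- file.path(out_dir, "aligned_video.rds.json")
      # crops are kept in a JSON container alongside the track
      write_atomic(crops_path, function(tmp)
        jsonlite::write_json(list(crops = video$crops,
                                  centroid_xy = video$centroid_xy,
                                  heading = video$heading,
                                  valid = video$valid, fps = video$fps,
                                  mm_per_px = video$mm_per_px),
                             tmp, digits = NA, auto_unbox = TRUE))
      list(track = track_path, aligned = crops_path)
    },
    features = {
      fc <- cfg$features %||% list()
      aligned_path <- need(file.path(cfg$paths$out_dir %||% out_dir,
                                     "aligned_video.rds.json"),
                           "extract-stage aligned video")
      o <- jsonlite::read_json(aligned_path, simplifyVector = TRUE)
      video <- structure(
        list(crops = o$crops, centroid_xy = o$centroid_xy,
             heading = o$heading, valid = o$valid, fps = o$fps,
             mm_per_px = o$mm_per_px),
        class = "aligned_pose_video")
      series <- if ((fc$method %||% "pca") == "pca")
        fit_pca(video, fc$n_components %||% 10)
      else
        random_projection(video, fc$n_components %||% 10, seed = seed)
      p <- file.path(out_dir, "series.csv")
      write_pose_series_csv(series, p, meta)
      list(series = p)
    },
    train = {
      mc <- cfg$model %||% list()
      series <- read_pose_series_csv(need(
        cfg$paths$series_csv %||% file.path(out_dir, "series.csv"),
        "a pose series CSV"))
      config_fit <- fit_config(
        n_sweeps = mc$n_sweeps %||% 100, n_burnin = mc$n_burnin %||% 50,
        seed = seed, K_max = mc$K_max %||% 100,
        ar_lag = mc$ar_lag %||% 3,
        target_mean_duration_s = mc$target_mean_duration_s %||% 0.3,
        gamma = mc$gamma %||% 10, alpha = mc$alpha %||% 5,
        kappa = mc$kappa)
      fit <- fit_arhmm(series, config_fit)
      paths <- list(model = file.path(out_dir, "model.json"),
                    labels = file.path(out_dir, "labels.csv"),
                    diagnostics = file.path(out_dir, "diagnostics.csv"))
      write_arhmm_json(fit$model, paths$model, meta)
      write_labels_csv(fit$labels, paths$labels, meta)
      write_csv_meta(fit$diagnostics, paths$diagnostics, meta)
      paths
    },
    apply = {
      model <- read_arhmm_json(need(cfg$paths$model_json, "a model JSON"))
      series <- read_pose_series_csv(need(cfg$paths$series_csv,
                                          "a pose series CSV"))
      labels <- resample_labels(model, series, seed = seed)
      p <- file.path(out_dir, "labels.csv")
      write_labels_csv(labels, p, meta)
      list(labels = p)
    },
    analyze = {
      ac <- cfg$analysis %||% list()
      labels <- read_labels_csv(need(
        cfg$paths$labels_csv %||% file.path(out_dir, "labels.csv"),
        "a labels CSV"))
      u <- usages(labels, mode = ac$usage_mode %||% "frames")
      d <- durations(labels)
      P <- transition_matrix(labels)
      map <- build_state_map(u, P, min_usage = ac$min_usage %||% 0,
                             min_edge_p = ac$min_edge_p %||% 0)
      paths <- list(usages = file.path(out_dir, "usages.csv"),
                    durations = file.path(out_dir, "durations.csv"),
                    transitions = file.path(out_dir, "transitions.csv"),
                    state_map = file.path(out_dir, "state_map.graphml"))
      write_csv_meta(u, paths$usages, meta)
      write_csv_meta(d, paths$durations, meta)
      write_csv_meta(tibble(from = rep(as.integer(rownames(P)), ncol(P)),
                            to = rep(as.integer(colnames(P)),
                                     each = nrow(P)),
                            p = as.numeric(P)),
                     paths$transitions, meta)
      write_state_map(map, paths$state_map)
      paths
    },
    compare = {
      ac <- cfg$analysis %||% list()
      read_group <- function(paths_str) {
        files <- strsplit(paths_str, ";")[[1]]
        lapply(files, function(f) read_labels_csv(need(f, "a labels CSV")))
      }
      la <- read_group(cfg$paths$labels_csv_a %||%
                         abort("paths.labels_csv_a is required"))
      lb <- read_group(cfg$paths$labels_csv_b %||%
                         abort("paths.labels_csv_b is required"))
      cmp <- compare_usages(la, lb,
                            n_permutations = ac$n_permutations %||% 1000,
                            fdr = ac$fdr %||% 0.05, seed = seed,
                            mode = ac$usage_mode %||% "frames")
      p <- file.path(out_dir, "usage_comparison.csv")
      write_usage_comparison_csv(cmp, p)
      list(comparison = p)
    },
    evaluate = {
      vc <- cfg$evaluate %||% list()
      mc <- cfg$model %||% list()
      series <- read_pose_series_csv(need(
        cfg$paths$series_csv %||% file.path(out_dir, "series.csv"),
        "a pose series CSV"))
      Y <- series$values
      n_train <- floor((vc$train_fraction %||% 0.8) * nrow(Y))
      train <- pose_series(Y[seq_len(n_train), , drop = FALSE],
                           fps = series$fps, source = series$source)
      test <- pose_series(Y[(n_train + 1):nrow(Y), , drop = FALSE],
                          fps = series$fps, source = series$source)
      config_fit <- fit_config(
        n_sweeps = mc$n_sweeps %||% 50, n_burnin = mc$n_burnin %||% 25,
        seed = seed, K_max = mc$K_max %||% 40,
        ar_lag = mc$ar_lag %||% 3,
        target_mean_duration_s = mc$target_mean_duration_s %||% 0.3,
        gamma = mc$gamma %||% 10, alpha = mc$alpha %||% 5)
      fit <- fit_arhmm(train, config_fit)
      base_ar <- ar_baseline(train, ar_lag = config_fit$ar_lag)
      base_gmm <- gmm_baseline(train, test,
                               n_components = vc$gmm_components %||% 10,
                               seed = seed)
      report <- heldout_compare(train, test,
                                list(arhmm = fit, ar_continuous = base_ar,
                                     gmm = base_gmm))
      p <- file.path(out_dir, "eval_report.csv")
      write_csv_meta(as_tibble(report), p, meta)
      txt <- file.path(out_dir, "eval_report.txt")
      write_atomic(txt, function(tmp) writeLines(c(
        "held-out model comparison (per-frame log likelihood):",
        sprintf("  %-14s %10.4f", report$model, report$per_frame_loglik)),
        tmp))
      list(report = p, summary = txt)
    })
  write_run_log(out_dir, stage, cfg, seed,
                proc.time()[["elapsed"]] - t0)
  invisible(written)
}
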