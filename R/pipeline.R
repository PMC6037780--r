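# file-based stage runner: every stage reads its inputs from out_dir and
# writes plain artifacts there, so partial reruns and inspection are easy

write_norm_traces <- function(x, path) {
  df <- as.data.frame(t(x$values))
  names(df) <- roi_names(x$roi_ids)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(first_valid_frame = x$first_valid_frame,
               frame_interval_s = x$frame_interval_s,
               normalized = isTRUE(x$normalized))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

read_norm_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(values = unname(t(as.matrix(df))),
                 roi_ids = parse_roi_names(names(df)),
                 frame_interval_s = meta$frame_interval_s,
                 first_valid_frame = as.integer(meta$first_valid_frame),
                 clip_value = NULL,
                 normalized = isTRUE(meta$normalized)),
            class = "dff_traces")
}

pipeline_paths <- function(out_dir) {
  p <- function(f) file.path(out_dir, f)
  list(traces = p("traces.csv"), truth = p("truth.csv"),
       movie = p("movie.tif"), norm18 = p("norm18.csv"),
       norm9 = p("norm9.csv"), windows = p("windows.tif"),
       features = p("features.csv"), labels = p("labels.csv"),
       cluster_map = p("cluster_map.csv"), events = p("events.csv"),
       report = p("report.json"), stats = p("stats.json"),
       manifest = p("manifest.json"))
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", basename(path),
         ": run stage \"", produced_by, "\" first")
  path
}

PIPELINE_STAGES <- c("simulate", "preprocess", "windows", "features",
                     "classify", "events", "evaluate", "stats", "map")

#' Run the classification pipeline on disk
#'
#' Executes the requested stages in order, reading and writing plain files
#' under `out_dir`: `simulate` (synthetic traces, ground truth and movie),
#' `preprocess` (normalized 18- and 9-ROI dF/F), `windows` (multi-page
#' TIFF of window images), `features`, `classify` (per-window cluster and
#' label), `events`, `evaluate` (scored against the ground truth),
#' `stats` (frequencies, durations, transition matrix) and `map`
#' (behavior and dominant-pattern maps of the movie). A manifest recording
#' stages, paths, the config hash and the seed is written at the end;
#' identical config and seed give an identical manifest hash and
#' bitwise-identical artifacts.
#'
#' @param out_dir Output directory (created if missing).
#' @param stages Subset of the stage names, in pipeline order.
#' @param config A [run_config()].
#' @param sim A [sim_config()] (used by `simulate`).
#' @param seed Integer seed.
#' @param with_movie Should `simulate` also render the volumetric movie
#'   (needed by `map`)?
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, stages = PIPELINE_STAGES,
                         config = run_config(), sim = sim_config(),
                         seed = config$seed, with_movie = "map" %in% stages) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(out_dir)

  for (stage in stages) {
    message("stage: ", stage)
    switch(stage,
    simulate = {
      truth <- simulate_events(sim, seed)
      ren <- render_roi_traces(truth, sim, seed)
      write_roi_traces(ren$traces, p$traces)
      write_event_table(truth, p$truth)
      if (with_movie) {
        mov <- render_volume_movie(truth, sim, seed)
        write_volume_movie(mov$movie, p$movie)
      }
    },
    preprocess = {
      tr <- read_roi_traces(need_artifact(p$traces, "simulate"),
                            sim$frame_interval_s)
      dff <- compute_dff(tr, config$baseline_window, config$clip_value)
      norm18 <- minmax_normalize(dff)
      write_norm_traces(norm18, p$norm18)
      write_norm_traces(compress_lr(norm18), p$norm9)
    },
    windows = {
      norm9 <- read_norm_traces(need_artifact(p$norm9, "preprocess"))
      stack <- make_windows(norm9, config$window_size, config$image_side)
      write_window_stack(stack, p$windows)
    },
    features = {
      norm9 <- read_norm_traces(need_artifact(p$norm9, "preprocess"))
      stack <- make_windows(norm9, config$window_size, config$image_side)
      bb <- build_backbone(config$backbone, seed = seed)
      feats <- extract_features(stack, bb)
      utils::write.csv(as.data.frame(feats), p$features, row.names = FALSE)
    },
    classify = {
      feats <- as.matrix(utils::read.csv(
        need_artifact(p$features, "features")))
      norm9 <- read_norm_traces(need_artifact(p$norm9, "preprocess"))
      stack <- make_windows(norm9, config$window_size, config$image_side,
                            encode = FALSE)
      asg <- cluster_windows(feats, config$n_clusters)
      map <- auto_label_clusters(mean_cluster_windows(asg, stack),
                                 config$label_thresholds)
      lab <- refine_unlabeled(asg, map, feats, stack,
                              config$label_thresholds)
      utils::write.csv(data.frame(window = seq_along(asg$cluster),
                                  center = stack$centers,
                                  cluster = asg$cluster,
                                  label = lab),
                       p$labels, row.names = FALSE)
      utils::write.csv(as.data.frame(map), p$cluster_map, row.names = FALSE)
    },
    events = {
      lab <- utils::read.csv(need_artifact(p$labels, "classify"),
                             colClasses = c(label = "character"))
      norm9 <- read_norm_traces(need_artifact(p$norm9, "preprocess"))
      norm18 <- read_norm_traces(need_artifact(p$norm18, "preprocess"))
      series <- window_labels_to_series(lab$label, lab$center,
                                        ncol(norm9$values),
                                        norm9$first_valid_frame)
      ev <- extract_events(series, norm9$frame_interval_s, norm9, norm18)
      write_event_table(ev, p$events)
    },
    evaluate = {
      ev <- read_event_table(need_artifact(p$events, "events"))
      truth <- read_event_table(need_artifact(p$truth, "simulate"))
      rep <- evaluate_events(ev, truth, config$overlap_threshold)
      jsonlite::write_json(rep, p$report, dataframe = "rows", na = "null")
    },
    stats = {
      ev <- read_event_table(need_artifact(p$events, "events"))
      norm9 <- read_norm_traces(need_artifact(p$norm9, "preprocess"))
      total_s <- ncol(norm9$values) * norm9$frame_interval_s
      tm <- transition_matrix(ev)
      st <- list(
        frequency_per_min = as.list(event_frequency(ev, total_s)),
        duration_mean_s = lapply(split(ev$duration_s, ev$class), mean),
        transition_states = tm$states,
        transition_probabilities = tm$probabilities)
      jsonlite::write_json(st, p$stats, auto_unbox = TRUE, digits = NA)
      utils::write.csv(as.data.frame(tm$probabilities),
                       file.path(out_dir, "transitions.csv"))
    },
    map = {
      mov <- read_volume_movie(need_artifact(p$movie, "simulate"),
                               n_z = as.integer(sim$movie_dims[1]),
                               frame_interval_s = sim$frame_interval_s)
      lab <- utils::read.csv(need_artifact(p$labels, "classify"),
                             colClasses = c(label = "character"))
      vdff <- voxel_dff(mov, config$baseline_window)
      series <- window_labels_to_series(lab$label, lab$center,
                                        dim(vdff$values)[1],
                                        vdff$first_valid_frame)
      maps <- lapply(c(AT = "AT", BW = "BW", FW = "FW", PT = "PT"),
                     function(cl) behavior_map(vdff, series, cl))
      for (cl in names(maps))
        write_map(maps[[cl]], file.path(out_dir, paste0("map_", cl, ".tif")))
      dom <- dominant_map(maps, config$r_display_threshold)
      write_map(dom, file.path(out_dir, "map_dominant.tif"))
    })
  }

  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(list(config = unclass(config), sim = unclass(sim), seed = seed),
          cfg_file, version = 2)
  manifest <- list(stages = stages,
                   paths = lapply(p[names(p) != "manifest"], basename),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("fictivemotor")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' One-command synthetic demo
#'
#' Runs the full pipeline (simulation through correlation maps) on a short
#' synthetic recording.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_frames Length of the simulated recording (default 400).
#' @param backbone Feature backbone kind.
#' @return The pipeline manifest, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, n_frames = 400L,
                     backbone = "vgg16-random") {
  run_pipeline(out_dir,
               config = run_config(backbone = backbone, seed = seed),
               sim = sim_config(n_frames = n_frames),
               seed = seed)
}
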