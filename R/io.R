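#' ROI trace set
#'
#' Container for raw segmental fluorescence: one row per hemisegmental ROI,
#' one column per imaging frame, with the hemisegment identity of each row
#' and the frame interval in seconds. Either the full 18-ROI layout (T2-A7,
#' left and right) or the 9-ROI layout (left/right already compressed) is
#' accepted.
#'
#' @param values Numeric matrix `[n_rois x n_frames]` of raw fluorescence.
#' @param roi_ids Data frame with columns `segment` (in [SEGMENTS]) and
#'   `side` (`"L"`/`"R"`, or `NA` for compressed traces), one row per ROI.
#' @param frame_interval_s Seconds per imaging frame (> 0).
#'
#' @return An object of class `roi_traces`.
#' @export
roi_traces <- function(values, roi_ids, frame_interval_s) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) == nrow(roi_ids),
            is.finite(frame_interval_s), frame_interval_s > 0)
  if (!all(is.finite(values))) stop("non-finite fluorescence values")
  if (!nrow(values) %in% c(9L, 18L))
    stop("expected 18 hemisegmental or 9 compressed ROIs, got ", nrow(values))
  dimnames(values) <- NULL
  roi_ids$segment <- as.character(roi_ids$segment)
  if (!all(roi_ids$segment %in% SEGMENTS))
    stop("unknown segment name(s): ",
         paste(setdiff(roi_ids$segment, SEGMENTS), collapse = ", "))
  ord <- order(match(roi_ids$segment, SEGMENTS),
               match(as.character(roi_ids$side), c("L", "R")))
  values <- values[ord, , drop = FALSE]
  roi_ids <- roi_ids[ord, , drop = FALSE]
  rownames(roi_ids) <- NULL
  if (nrow(values) == 18L) {
    want <- paste(rep(SEGMENTS, each = 2), c("L", "R"))
    have <- paste(roi_ids$segment, roi_ids$side)
    if (!identical(have, want)) stop("incomplete hemisegment set")
  } else {
    if (!identical(roi_ids$segment, SEGMENTS))
      stop("compressed traces must cover each of T2-A7 exactly once")
  }
  structure(list(values = values, roi_ids = roi_ids,
                 frame_interval_s = frame_interval_s),
            class = "roi_traces")
}

roi_names <- function(roi_ids) {
  ifelse(is.na(roi_ids$side), roi_ids$segment,
         paste0(roi_ids$segment, "_", roi_ids$side))
}

parse_roi_names <- function(nms) {
  m <- regmatches(nms, regexec("^([TA][0-9]+)(?:_([LR]))?$", nms))
  bad <- nms[lengths(m) == 0 | !vapply(m, function(x) x[2] %in% SEGMENTS, TRUE)]
  if (length(bad)) stop("unrecognized ROI column name(s): ",
                        paste(bad, collapse = ", "))
  data.frame(segment = vapply(m, `[`, "", 2),
             side = ifelse(vapply(m, `[`, "", 3) == "", NA_character_,
                           vapply(m, `[`, "", 3)))
}

#' Read / write ROI traces as CSV
#'
#' The file is a comma-separated table with one header row naming the ROIs
#' (`"A3_L"` style for hemisegmental traces, bare segment names for
#' compressed traces) and one row per frame. The frame interval is carried
#' as metadata, not inferred from the file.
#'
#' @param path CSV file path.
#' @param frame_interval_s Seconds per frame.
#' @return A [roi_traces()] object (reader) or `path`, invisibly (writer).
#' @export
read_roi_traces <- function(path, frame_interval_s) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate ROI column names")
  if (nrow(df) < 2) stop("fewer than 2 frames")
  if (!all(vapply(df, is.numeric, TRUE))) stop("non-numeric cells in trace file")
  if (!ncol(df) %in% c(9L, 18L))
    stop("incomplete hemisegment set: expected 18 or 9 ROI columns, got ",
         ncol(df))
  roi_traces(t(as.matrix(df)), parse_roi_names(names(df)), frame_interval_s)
}

#' @rdname read_roi_traces
#' @param traces A [roi_traces()] object.
#' @export
write_roi_traces <- function(traces, path) {
  stopifnot(inherits(traces, "roi_traces"))
  df <- as.data.frame(t(traces$values))
  names(df) <- roi_names(traces$roi_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Volumetric movie
#'
#' A registered calcium-imaging movie as a 4-D array ordered
#' `[t, z, y, x]`, with the frame (volume) interval in seconds.
#'
#' @param voxels 4-D numeric array `[t, z, y, x]`.
#' @param frame_interval_s Seconds per volume.
#' @return An object of class `volume_movie`.
#' @export
volume_movie <- function(voxels, frame_interval_s) {
  stopifnot(length(dim(voxels)) == 4, is.finite(frame_interval_s),
            frame_interval_s > 0)
  if (!all(is.finite(voxels))) stop("non-finite voxel values")
  structure(list(voxels = voxels, frame_interval_s = frame_interval_s),
            class = "volume_movie")
}

#' Read / write a volumetric movie as multi-page TIFF
#'
#' Pages are t-major: all `n_z` planes of volume 0, then volume 1, and so
#' on; the page count must be divisible by `n_z`. Samples are stored as
#' 32-bit floats scaled into `[0, 1]`; the intensity scale, `n_z` and the
#' frame interval are kept in a JSON sidecar (`<path>.meta.json`), which
#' the reader uses for its defaults when present.
#'
#' @param path TIFF file path.
#' @param n_z Number of z planes per volume (1 for single-plane movies;
#'   `NULL` to take it from the sidecar).
#' @param frame_interval_s Seconds per volume (`NULL`: from the sidecar).
#' @return A [volume_movie()] (reader) or `path`, invisibly (writer).
#' @export
read_volume_movie <- function(path, n_z = NULL, frame_interval_s = NULL) {
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (is.null(n_z)) n_z <- if (!is.null(meta$n_z)) meta$n_z else 1L
  if (is.null(frame_interval_s))
    frame_interval_s <- if (!is.null(meta$frame_interval_s))
      meta$frame_interval_s else 1
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_z != 0)
    stop("page count ", length(pages), " not divisible by n_z = ", n_z)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
    stop("inconsistent page shapes")
  n_t <- length(pages) %/% n_z
  vox <- array(0, dim = c(n_t, n_z, shp[1], shp[2]))
  for (t in seq_len(n_t)) for (z in seq_len(n_z))
    vox[t, z, , ] <- pages[[(t - 1L) * n_z + z]] * scale
  volume_movie(vox, frame_interval_s)
}

#' @rdname read_volume_movie
#' @param movie A [volume_movie()] object.
#' @export
write_volume_movie <- function(movie, path) {
  stopifnot(inherits(movie, "volume_movie"))
  d <- dim(movie$voxels)
  scale <- max(movie$voxels, 1e-12)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) for (z in seq_len(d[2]))
    pages[[(t - 1L) * d[2] + z]] <- movie$voxels[t, z, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, n_z = d[2],
                            frame_interval_s = movie$frame_interval_s),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Event tables
#'
#' A table of contiguous same-label episodes: columns `class` (a motor
#' label), `start_frame` / `end_frame` (0-based, half-open), `duration_s`,
#' `intensity` (maximum normalized dF/F during the event, `NA` if not
#' computed) and `mean_asymmetry` (`NA` if not computed). Events must not
#' overlap, regardless of class.
#'
#' @param class,start_frame,end_frame,duration_s,intensity,mean_asymmetry
#'   Column vectors, recycled to a common length.
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(class = character(), start_frame = integer(),
                        end_frame = integer(), duration_s = numeric(),
                        intensity = NA_real_, mean_asymmetry = NA_real_) {
  n <- length(class)
  df <- data.frame(class = as.character(class),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame),
                   duration_s = rep(as.numeric(duration_s),
                                    length.out = n),
                   intensity = rep(as.numeric(intensity), length.out = n),
                   mean_asymmetry = rep(as.numeric(mean_asymmetry),
                                        length.out = n))
  validate_event_table(df)
}

validate_event_table <- function(df) {
  assert_label(df$class)
  if (any(df$end_frame <= df$start_frame))
    stop("event with end_frame <= start_frame")
  if (nrow(df) > 1) {
    o <- order(df$start_frame)
    if (any(df$start_frame[o][-1] < df$end_frame[o][-nrow(df)]))
      stop("overlapping events")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write an event table as CSV
#'
#' Round-trip safe: `read_event_table(write_event_table(x, p))` equals `x`.
#' Frame spans are stored 0-based and half-open.
#'
#' @param events An [event_table()].
#' @param path CSV file path.
#' @return The table (reader) or `path`, invisibly (writer).
#' @export
write_event_table <- function(events, path) {
  validate_event_table(as.data.frame(events))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(class = "character"))
  need <- c("class", "start_frame", "end_frame", "duration_s",
            "intensity", "mean_asymmetry")
  if (!all(need %in% names(df)))
    stop("event table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  validate_event_table(df[need])
}
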