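#' Expand per-window labels to a per-frame label series
#'
#' Each valid frame in `4 .. T - 5` (0-based) takes the label of the window
#' centered on it; the 4 leading frames copy the first window's label and
#' the 4 trailing frames the last window's, compensating the frames that
#' carry no window center. 2024 window labels therefore expand to a series
#' of 2032 frames.
#'
#' @param labels Character vector of per-window motor labels.
#' @param centers 0-based window centers, `4 .. T - 5` consecutive
#'   (see [make_windows()]).
#' @param n_valid_frames Length `T` of the valid-frame axis.
#' @param first_valid_frame Offset of valid frame 0 in the original
#'   recording (carried into event tables downstream).
#' @return A `label_series`: character vector of length `n_valid_frames`
#'   with attribute `first_valid_frame`.
#' @export
window_labels_to_series <- function(labels, centers, n_valid_frames,
                                    first_valid_frame = 0L) {
  n_w <- length(labels)
  T <- as.integer(n_valid_frames)
  if (length(centers) != n_w) stop("labels/centers length mismatch")
  half <- if (n_w > 0) centers[1] else 0L
  if (n_w > 0 && !identical(as.integer(centers),
                            seq.int(half, length.out = n_w)))
    stop("centers must be consecutive")
  if (n_w + 2L * half != T)
    stop("window count ", n_w, " inconsistent with ", T, " valid frames")
  assert_label(labels)
  series <- c(rep(labels[1], half), labels, rep(labels[n_w], half))
  structure(series, first_valid_frame = as.integer(first_valid_frame),
            class = "label_series")
}

#' Collapse a label series into an event table
#'
#' Maximal runs of identical labels become events (consecutive frames of
#' one label are one activity); quiescence and unlabeled runs are retained
#' as events. Frame spans are reported in original-recording coordinates
#' (the series' `first_valid_frame` offset is added), 0-based and
#' half-open. When normalized traces are supplied, each event also gets its
#' intensity (maximum normalized dF/F over all ROIs and frames of the
#' event) and, from 18-ROI traces, its mean left-right asymmetry index.
#'
#' @param series A `label_series` (or plain character vector of labels).
#' @param frame_interval_s Seconds per frame.
#' @param norm Optional normalized `dff_traces` (9 or 18 ROIs) for
#'   intensities.
#' @param norm18 Optional normalized 18-ROI `dff_traces` for asymmetry.
#' @return An [event_table()].
#' @export
extract_events <- function(series, frame_interval_s, norm = NULL,
                           norm18 = NULL) {
  off <- attr(series, "first_valid_frame")
  if (is.null(off)) off <- 0L
  r <- rle(as.character(series))
  if (!length(r$lengths)) return(event_table())
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  ev <- event_table(class = r$values,
                    start_frame = start + off, end_frame = end + off,
                    duration_s = r$lengths * frame_interval_s)
  if (!is.null(norm)) {
    ev$intensity <- vapply(seq_len(nrow(ev)), function(i) {
      cols <- (start[i] + 1L):end[i]
      max(norm$values[, cols])
    }, 0)
  }
  if (!is.null(norm18)) {
    ai <- asymmetry_index(norm18)
    ev$mean_asymmetry <- vapply(seq_len(nrow(ev)), function(i) {
      mean(ai[(start[i] + 1L):end[i]], na.rm = TRUE)
    }, 0)
  }
  ev
}

#' Expand an event table back to a label series
#'
#' Inverse of [extract_events()] for gap-free tables; frames not covered by
#' any event are marked `UL`.
#'
#' @param events An [event_table()].
#' @param n_frames Series length (original-recording frames).
#' @param first_valid_frame Offset subtracted from the stored spans.
#' @return A `label_series` of length `n_frames`.
#' @export
events_to_series <- function(events, n_frames,
                             first_valid_frame = 0L) {
  series <- rep("UL", n_frames)
  for (i in seq_len(nrow(events))) {
    s <- events$start_frame[i] - first_valid_frame
    e <- events$end_frame[i] - first_valid_frame
    s <- max(s, 0L); e <- min(e, n_frames)
    if (e > s) series[(s + 1L):e] <- events$class[i]
  }
  structure(series, first_valid_frame = as.integer(first_valid_frame),
            class = "label_series")
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Score predicted events against ground truth
#'
#' A ground-truth event is a hit when some predicted event of the same
#' class overlaps at least `overlap_threshold` of the truth span; a
#' predicted event is a false alarm when it overlaps no truth event of its
#' class at all. Rates are per class: `hits / n_truth` and
#' `false_alarms / n_pred`. Classes with no truth events get `NA` hit
#' rates (undefined, not zero); classes with no predictions get `NA` false
#' alarm rates.
#'
#' @param pred,truth [event_table()]s over the same frame span.
#' @param overlap_threshold Minimum covered fraction of a truth event
#'   (default 0.5).
#' @param classes Classes to score (default: the four motor patterns).
#' @return Data frame with one row per class: `n_truth`, `n_pred`, `hits`,
#'   `false_alarms`, `hit_rate`, `false_alarm_rate`.
#' @export
evaluate_events <- function(pred, truth, overlap_threshold = 0.5,
                            classes = c("AT", "BW", "FW", "PT")) {
  res <- lapply(classes, function(cl) {
    p <- pred[pred$class == cl, , drop = FALSE]
    t <- truth[truth$class == cl, , drop = FALSE]
    hits <- 0L
    for (i in seq_len(nrow(t))) {
      ov <- overlap_len(p$start_frame, p$end_frame,
                        t$start_frame[i], t$end_frame[i])
      span <- t$end_frame[i] - t$start_frame[i]
      if (any(ov >= overlap_threshold * span)) hits <- hits + 1L
    }
    fa <- 0L
    for (i in seq_len(nrow(p))) {
      ov <- overlap_len(t$start_frame, t$end_frame,
                        p$start_frame[i], p$end_frame[i])
      if (!any(ov > 0)) fa <- fa + 1L
    }
    data.frame(class = cl, n_truth = nrow(t), n_pred = nrow(p),
               hits = hits, false_alarms = fa,
               hit_rate = if (nrow(t)) hits / nrow(t) else NA_real_,
               false_alarm_rate = if (nrow(p)) fa / nrow(p) else NA_real_)
  })
  do.call(rbind, res)
}
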