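#' Rectified running-baseline dF/F
#'
#' For each ROI and frame `t` (0-based, `t >= baseline_window`) the baseline
#' `F_base(t)` is the mean of the preceding `baseline_window` frames
#' `F(t - baseline_window) .. F(t - 1)`, and
#' `dF/F(t) = max(0, F(t) / F_base(t) - 1)`: only rising calcium signal is
#' kept, and the running baseline absorbs slow fluorescence decay. Values
#' above `clip_value` are capped at `clip_value`. The first
#' `baseline_window` frames, which have no defined baseline, are dropped, so
#' an 18 x 2048 recording yields 2032 valid frames.
#'
#' @param traces A [roi_traces()] object with strictly positive values.
#' @param baseline_window Baseline length in frames (default 16).
#' @param clip_value Optional cap on dF/F (`NULL` to disable).
#' @return A `dff_traces` object: list with `values`
#'   `[n_rois x n_valid_frames]` (all `>= 0`), `roi_ids`,
#'   `frame_interval_s`, `first_valid_frame` (`= baseline_window`) and
#'   `clip_value`.
#' @export
compute_dff <- function(traces, baseline_window = 16L, clip_value = NULL) {
  stopifnot(inherits(traces, "roi_traces"))
  vals <- dff_matrix(traces$values, baseline_window, clip_value)
  structure(list(values = vals, roi_ids = traces$roi_ids,
                 frame_interval_s = traces$frame_interval_s,
                 first_valid_frame = as.integer(baseline_window),
                 clip_value = clip_value,
                 normalized = FALSE),
            class = "dff_traces")
}

# core used both for ROI traces and (flattened) voxel movies; X is
# [n_series x n_frames], rows are independent series
dff_matrix <- function(X, baseline_window, clip_value = NULL) {
  w <- as.integer(baseline_window)
  n <- ncol(X)
  if (n <= w) stop("recording too short: ", n, " frames for a ", w,
                   "-frame baseline")
  if (any(X <= 0)) stop("nonpositive fluorescence values")
  cs <- X
  for (j in 2:n) cs[, j] <- cs[, j - 1L] + X[, j]
  lag <- cbind(0, cs[, seq_len(n - w - 1L) , drop = FALSE])
  # baseline for output frame j0 = w..n-1 (0-based): mean of cols j0-w..j0-1
  base <- (cs[, w:(n - 1L), drop = FALSE] - lag) / w
  out <- X[, (w + 1L):n, drop = FALSE] / base - 1
  out[out < 0] <- 0
  if (!is.null(clip_value)) out[out > clip_value] <- clip_value
  dimnames(out) <- NULL
  out
}

#' Global min-max normalization of dF/F
#'
#' Scales the whole dF/F matrix to `[0, 1]` with one global minimum and
#' maximum, preserving relative intensity between segments and frames. A
#' constant matrix maps to all zeros.
#'
#' @param dff A `dff_traces` object from [compute_dff()].
#' @return The same structure with `values` in `[0, 1]` and
#'   `normalized = TRUE`.
#' @export
minmax_normalize <- function(dff) {
  stopifnot(inherits(dff, "dff_traces"))
  v <- dff$values
  rng <- range(v)
  dff$values <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
                else array(0, dim(v))
  dff$normalized <- TRUE
  dff
}

#' Compress left/right hemisegments to segmental traces
#'
#' Reduces 18 hemisegmental ROIs to 9 segmental traces by taking, per
#' segment and frame, the maximum of the left and right values, so that
#' activity on either side of the animal is retained. Segment order is
#' preserved.
#'
#' @param x A `dff_traces` (or [roi_traces()]) object with 18 paired rows.
#' @return The same class of object with 9 rows, `side = NA`.
#' @export
compress_lr <- function(x) {
  stopifnot(inherits(x, c("dff_traces", "roi_traces")))
  ids <- x$roi_ids
  if (nrow(ids) != 18L || !all(table(ids$segment) == 2))
    stop("compress_lr needs 18 ROIs with paired L/R per segment")
  li <- which(ids$side == "L")[match(SEGMENTS, ids$segment[ids$side == "L"])]
  ri <- which(ids$side == "R")[match(SEGMENTS, ids$segment[ids$side == "R"])]
  x$values <- pmax(x$values[li, , drop = FALSE], x$values[ri, , drop = FALSE])
  x$roi_ids <- data.frame(segment = SEGMENTS, side = NA_character_)
  x
}

#' Optional centered moving-average smoothing
#'
#' A plain temporal box filter, off by default everywhere in the pipeline:
#' the running-baseline dF/F already suppresses slow drift, so this exists
#' only for exploratory display.
#'
#' @param x A `roi_traces` or `dff_traces` object.
#' @param k Odd window length in frames.
#' @return The object with each row replaced by its centered `k`-frame mean
#'   (edges use shrunken windows).
#' @export
temporal_smooth <- function(x, k = 3L) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  v <- x$values
  n <- ncol(v)
  out <- v
  for (j in seq_len(n)) {
    i <- max(1L, j - h):min(n, j + h)
    out[, j] <- rowMeans(v[, i, drop = FALSE])
  }
  x$values <- out
  x
}
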