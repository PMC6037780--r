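#' Event frequency per class
#'
#' @param events An [event_table()].
#' @param total_time_s Recording duration in seconds (> 0).
#' @param classes Classes to report.
#' @return Named numeric vector of events per minute.
#' @export
event_frequency <- function(events, total_time_s,
                            classes = c("AT", "BW", "FW", "PT")) {
  stopifnot(total_time_s > 0)
  counts <- vapply(classes, function(cl) sum(events$class == cl), 0L)
  counts / total_time_s * 60
}

#' Intensity of one event
#'
#' The maximum normalized dF/F over all ROIs and all frames of the event.
#'
#' @param event One-row subset of an [event_table()].
#' @param norm A normalized `dff_traces` object aligned to the same
#'   recording.
#' @return Scalar intensity.
#' @export
event_intensity <- function(event, norm) {
  stopifnot(inherits(norm, "dff_traces"), nrow(event) == 1)
  s <- event$start_frame - norm$first_valid_frame
  e <- event$end_frame - norm$first_valid_frame
  if (s < 0 || e > ncol(norm$values)) stop("event outside the trace span")
  max(norm$values[, (s + 1L):e])
}

#' Left-right asymmetry index
#'
#' Per frame, the absolute difference between the maxima of the left and
#' right normalized dF/F, divided by the maximum over all 18 ROIs: 0 for
#' perfectly symmetric activity, 1 for fully one-sided activity, `NA`
#' (undefined) for silent frames.
#'
#' @param norm18 A normalized 18-ROI `dff_traces`.
#' @param frames Optional 1-based valid-frame indices (default: all).
#' @return Numeric vector of indices in `[0, 1]` (or `NA`).
#' @export
asymmetry_index <- function(norm18, frames = NULL) {
  stopifnot(inherits(norm18, "dff_traces"), nrow(norm18$roi_ids) == 18)
  v <- norm18$values
  if (!is.null(frames)) v <- v[, frames, drop = FALSE]
  li <- norm18$roi_ids$side == "L"
  mx_l <- apply(v[li, , drop = FALSE], 2, max)
  mx_r <- apply(v[!li, , drop = FALSE], 2, max)
  mx <- pmax(mx_l, mx_r)
  ifelse(mx > 0, abs(mx_l - mx_r) / mx, NA_real_)
}

#' Markov transition matrix over event classes
#'
#' Drops events outside `states` (unlabeled events are always dropped,
#' which concatenates their neighbors and can create same-state
#' transitions), counts ordered pairs of consecutive remaining events, and
#' row-normalizes. Rows with no outgoing transitions are `NaN` and listed
#' in the `undefined_rows` attribute.
#'
#' @param events An [event_table()] in temporal order.
#' @param states States to keep, a subset of the five named patterns.
#' @return A `transition_matrix`: list with `states`, integer `counts` and
#'   row-stochastic `probabilities`.
#' @export
transition_matrix <- function(events,
                              states = c("AT", "BW", "FW", "PT", "QS")) {
  states <- setdiff(states, "UL")
  assert_label(states)
  seq_st <- events$class[order(events$start_frame)]
  seq_st <- seq_st[seq_st %in% states]
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  if (length(seq_st) < 2) {
    warning("fewer than 2 retained events; empty transition matrix")
    probs <- counts * NaN
  } else {
    for (i in seq_len(length(seq_st) - 1L))
      counts[seq_st[i], seq_st[i + 1L]] <-
        counts[seq_st[i], seq_st[i + 1L]] + 1L
    rs <- rowSums(counts)
    probs <- counts / ifelse(rs > 0, rs, NA)
  }
  structure(list(states = states, counts = counts, probabilities = probs,
                 undefined_rows = states[rowSums(counts) == 0]),
            class = "transition_matrix")
}

#' End-aligned average activity per motor pattern
#'
#' For each class, extracts a fixed window of normalized traces around each
#' event's end point and averages across events, reproducing the
#' "aligned at the end of the pattern" view of average motor dynamics.
#' Segments truncated by the recording edges are excluded. Mean and
#' standard deviation of event durations are reported alongside.
#'
#' @param events An [event_table()].
#' @param norm A normalized `dff_traces` aligned to the same recording.
#' @param window_before_s,window_after_s Seconds before / after the event
#'   end to include (defaults 4 and 2).
#' @param classes Classes to profile.
#' @return An `aligned_profile`: per class a list with `profile`
#'   (`[n_rois x aligned_frames]` mean trace), `n_events`,
#'   `duration_mean_s`, `duration_sd_s`; plus attributes `frames_before`
#'   and `frames_after`. Classes with no complete segment are excluded
#'   with a warning.
#' @export
aligned_average <- function(events, norm, window_before_s = 4,
                            window_after_s = 2,
                            classes = c("AT", "BW", "FW", "PT", "QS")) {
  stopifnot(inherits(norm, "dff_traces"))
  dt <- norm$frame_interval_s
  nb <- max(1L, as.integer(round(window_before_s / dt)))
  na_ <- max(1L, as.integer(round(window_after_s / dt)))
  T <- ncol(norm$values)
  out <- list()
  for (cl in classes) {
    ev <- events[events$class == cl, , drop = FALSE]
    segs <- list()
    for (i in seq_len(nrow(ev))) {
      anchor <- ev$end_frame[i] - norm$first_valid_frame  # frames after event
      if (anchor - nb >= 0 && anchor + na_ <= T)
        segs[[length(segs) + 1L]] <-
          norm$values[, (anchor - nb + 1L):(anchor + na_), drop = FALSE]
    }
    if (!length(segs)) {
      warning("no complete aligned segment for class ", cl)
      next
    }
    out[[cl]] <- list(
      profile = Reduce(`+`, segs) / length(segs),
      n_events = length(segs),
      duration_mean_s = mean(ev$duration_s),
      duration_sd_s = if (nrow(ev) > 1) stats::sd(ev$duration_s) else NA_real_)
  }
  structure(out, frames_before = nb, frames_after = na_,
            class = "aligned_profile")
}
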