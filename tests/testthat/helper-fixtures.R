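# small in-code fixtures shared across test files

make_traces <- function(values, frame_interval_s = 0.3) {
  ids <- data.frame(segment = rep(SEGMENTS, each = 2),
                    side = rep(c("L", "R"), 9))
  roi_traces(values, ids, frame_interval_s)
}

# constant-baseline 18-ROI recording, F = f0 everywhere
flat_traces <- function(n_frames, f0 = 100, frame_interval_s = 0.3) {
  make_traces(matrix(f0, 18, n_frames), frame_interval_s)
}

# normalized 9-segment trace object wrapped by hand
norm9_from_matrix <- function(v, first_valid_frame = 16L,
                              frame_interval_s = 0.3) {
  structure(list(values = v,
                 roi_ids = data.frame(segment = SEGMENTS,
                                      side = NA_character_),
                 frame_interval_s = frame_interval_s,
                 first_valid_frame = as.integer(first_valid_frame),
                 clip_value = NULL, normalized = TRUE),
            class = "dff_traces")
}

norm18_from_matrix <- function(v, first_valid_frame = 16L,
                               frame_interval_s = 0.3) {
  structure(list(values = v,
                 roi_ids = data.frame(segment = rep(SEGMENTS, each = 2),
                                      side = rep(c("L", "R"), 9)),
                 frame_interval_s = frame_interval_s,
                 first_valid_frame = as.integer(first_valid_frame),
                 clip_value = NULL, normalized = TRUE),
            class = "dff_traces")
}

# tiny window stack around given [9 x 8] windows without going through
# make_windows
stack_from_windows <- function(wins, image_side = 72L) {
  n <- length(wins)
  arr <- array(0, dim = c(9, 8, n))
  img <- array(0L, dim = c(image_side, image_side, 3, n))
  for (i in seq_len(n)) {
    arr[, , i] <- wins[[i]]
    img[, , , i] <- encode_window_image(wins[[i]], image_side)
  }
  structure(list(windows = arr, centers = seq_len(n) + 3L, images = img,
                 window_size = 8L, image_side = as.integer(image_side),
                 first_valid_frame = 16L, frame_interval_s = 0.3),
            class = "window_stack")
}

# a wave window: gaussian bump travelling across segments over 8 frames;
# direction "fw" = posterior to anterior
wave_window <- function(direction = c("fw", "bw"), amp = 0.9) {
  direction <- match.arg(direction)
  u <- (0:7) / 7
  pos <- if (direction == "fw") 9 - 8 * u else 1 + 8 * u
  amp * outer(1:9, pos, function(s, p) exp(-(s - p)^2 / (2 * 0.8^2)))
}

burst_window <- function(segments, amp = 0.8) {
  m <- matrix(0, 9, 8)
  m[segments, ] <- amp
  m
}
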