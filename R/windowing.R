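#' Decompose segmental traces into fixed x-t windows
#'
#' Slides an 8-frame window over the 9-segment normalized traces: the
#' window centered at valid frame `t` (0-based) covers frames
#' `t - 4 .. t + 3`, centers run `4 .. T - 5`, and the window count is
#' `T - window_size` (2032 valid frames give 2024 windows; the trailing
#' frame is uncovered by construction). Each window is also rendered as a
#' square 8-bit image via [encode_window_image()].
#'
#' @param norm9 A normalized, 9-row `dff_traces` object
#'   (see [minmax_normalize()], [compress_lr()]).
#' @param window_size Window length in frames (default 8).
#' @param image_side Side of the encoded square image (default 72); must be
#'   a multiple of both `window_size` and the segment count.
#' @param encode If `TRUE` (default) also build the 8-bit image stack.
#' @return A `window_stack`: list with `windows`
#'   `[n_segments x window_size x n_windows]`, `centers` (0-based valid
#'   frame indices, strictly increasing), `images`
#'   `[side x side x 3 x n_windows]` integer in 0..255 (rows = time,
#'   columns = segments) or `NULL`, `first_valid_frame` and
#'   `frame_interval_s` carried from the traces.
#' @export
make_windows <- function(norm9, window_size = 8L, image_side = 72L,
                         encode = TRUE) {
  stopifnot(inherits(norm9, "dff_traces"), isTRUE(norm9$normalized))
  v <- norm9$values
  ns <- nrow(v)
  if (ns != 9L) stop("expected 9 compressed segmental traces, got ", ns)
  w <- as.integer(window_size)
  T <- ncol(v)
  if (T < w) stop("series shorter than one window")
  n_w <- T - w
  half <- w %/% 2L
  centers <- if (n_w > 0) half + seq_len(n_w) - 1L else integer()
  windows <- array(0, dim = c(ns, w, n_w))
  for (i in seq_len(n_w))
    windows[, , i] <- v[, i:(i + w - 1L)]
  images <- NULL
  if (encode && n_w > 0) {
    images <- array(0L, dim = c(image_side, image_side, 3L, n_w))
    for (i in seq_len(n_w))
      images[, , , i] <- encode_window_image(windows[, , i], image_side)
  }
  structure(list(windows = windows, centers = centers, images = images,
                 window_size = w, image_side = as.integer(image_side),
                 first_valid_frame = norm9$first_valid_frame,
                 frame_interval_s = norm9$frame_interval_s),
            class = "window_stack")
}

#' Encode one x-t window as a square 8-bit RGB image
#'
#' Values in `[0, 1]` are mapped to `floor(v * 255)` and replicated into
#' pixel blocks by integer nearest-neighbor upsampling: rows are time
#' (`window_size -> side`), columns are segments anterior to posterior
#' (`n_segments -> side`), and the gray image is copied into all three
#' channels. With the 9 x 8 default each value fills a 9 x 8 pixel block.
#'
#' @param window Numeric matrix `[n_segments x window_size]` in `[0, 1]`.
#' @param image_side Output side in pixels.
#' @return Integer array `[side x side x 3]` with values in 0..255.
#' @export
encode_window_image <- function(window, image_side = 72L) {
  window <- as.matrix(window)
  if (any(window < 0 | window > 1)) stop("window values outside [0, 1]")
  ns <- nrow(window); w <- ncol(window)
  if (image_side %% ns != 0 || image_side %% w != 0)
    stop("image_side must be a multiple of both window dimensions")
  px <- matrix(as.integer(floor(window * 255)), ns, w)
  # rows = time upsampled x(side/w), cols = segments upsampled x(side/ns)
  img <- px[rep(seq_len(ns), each = image_side %/% ns),
            rep(seq_len(w), each = image_side %/% w), drop = FALSE]
  img <- t(img)
  array(img, dim = c(image_side, image_side, 3L))
}

#' Write a window-image stack as a multi-page TIFF
#'
#' One 8-bit grayscale-as-RGB page per window, in window order.
#'
#' @param stack A `window_stack` with encoded images.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_window_stack <- function(stack, path) {
  stopifnot(inherits(stack, "window_stack"), !is.null(stack$images))
  n <- dim(stack$images)[4]
  pages <- lapply(seq_len(n), function(i) stack$images[, , , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}
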