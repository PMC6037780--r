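#' Voxel-wise rectified dF/F of a volumetric movie
#'
#' Applies the same rectified running-baseline transform as
#' [compute_dff()] independently to every voxel. The first
#' `baseline_window` volumes are dropped, keeping the voxel series aligned
#' with the valid-frame axis of the ROI pipeline.
#'
#' @param movie A [volume_movie()] with positive intensities.
#' @param baseline_window Baseline length in frames (default 16).
#' @param clip_value Optional dF/F cap.
#' @return A `voxel_dff` object: list with `values`
#'   `[t_valid, z, y, x]`, `first_valid_frame` and `frame_interval_s`.
#' @export
voxel_dff <- function(movie, baseline_window = 16L, clip_value = NULL) {
  stopifnot(inherits(movie, "volume_movie"))
  d <- dim(movie$voxels)
  flat <- matrix(movie$voxels, d[1], prod(d[2:4]))  # [t x voxel]
  out <- dff_matrix(t(flat), baseline_window, clip_value)  # [voxel x t']
  vals <- array(t(out), dim = c(d[1] - baseline_window, d[2], d[3], d[4]))
  structure(list(values = vals,
                 first_valid_frame = as.integer(baseline_window),
                 frame_interval_s = movie$frame_interval_s),
            class = "voxel_dff")
}

# Pearson r of every row of V [n x T] against vector y; rows or targets
# with zero variance give NA
row_pearson <- function(V, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  if (sy == 0) return(rep(NA_real_, nrow(V)))
  Vc <- V - rowMeans(V)
  sv <- sqrt(rowSums(Vc^2))
  r <- as.vector(Vc %*% yc) / (sv * sy)
  r[sv == 0] <- NA_real_
  r
}

#' Behavior correlation map for one motor pattern
#'
#' Per voxel, the Pearson correlation between its rectified dF/F and the
#' binary indicator of the pattern (1 on frames labeled with the pattern,
#' 0 elsewhere). Zero-variance voxels are `NA`; a constant label vector
#' yields an all-`NA` map with a warning.
#'
#' @param vdff A `voxel_dff` object.
#' @param series A `label_series` over the same valid frames.
#' @param pattern Motor label to map.
#' @return 3-D array `[z, y, x]` of Pearson r in `[-1, 1]` or `NA`.
#' @export
behavior_map <- function(vdff, series, pattern) {
  stopifnot(inherits(vdff, "voxel_dff"))
  assert_label(pattern)
  d <- dim(vdff$values)
  if (length(series) != d[1])
    stop("label series length ", length(series),
         " does not match ", d[1], " movie frames")
  ind <- as.numeric(as.character(series) == pattern)
  if (length(unique(ind)) == 1)
    warning("label vector is constant; map is all NA")
  V <- t(matrix(vdff$values, d[1], prod(d[2:4])))
  array(row_pearson(V, ind), dim = d[2:4])
}

#' Dominant motor pattern per voxel
#'
#' Assigns each voxel the pattern whose behavior map has the highest
#' Pearson r, provided that maximum exceeds the display threshold;
#' sub-threshold voxels stay unassigned (`NA`). Ties go to the first
#' pattern in the list order.
#'
#' @param maps Named list of same-shaped behavior maps
#'   (e.g. `list(AT = ..., BW = ..., FW = ..., PT = ...)`).
#' @param threshold Minimum Pearson r (default 0.1).
#' @return Integer array shaped like the maps; values index into
#'   `names(maps)` (kept in attribute `patterns`), `NA` = unassigned.
#' @export
dominant_map <- function(maps, threshold = 0.1) {
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), TRUE)))
    stop("behavior maps have mismatched shapes")
  M <- vapply(maps, as.vector, numeric(prod(d)))
  M[is.na(M)] <- -Inf
  best <- max.col(M, ties.method = "first")
  top <- M[cbind(seq_len(nrow(M)), best)]
  best[!(top > threshold)] <- NA_integer_
  structure(array(best, dim = d), patterns = names(maps))
}

#' Seed-ROI correlation map with thresholded refinement
#'
#' The seed trace is the sum of raw fluorescence over the seed voxels,
#' converted to rectified dF/F; every voxel's dF/F is correlated against
#' it, and the refined ROI keeps the voxels whose Pearson r reaches the
#' refinement threshold. The refined trace is the sum of raw F(t) over
#' those voxels (single pass; set `iterate > 1` to repeat
#' refine-and-recorrelate for exploration).
#'
#' @param movie A [volume_movie()].
#' @param seed_mask Logical array `[z, y, x]`, non-empty.
#' @param baseline_window Baseline length in frames.
#' @param r_threshold Refinement threshold on Pearson r (default 0.05).
#' @param iterate Number of refine passes (default 1).
#' @return List with `r` (3-D Pearson-r array), `refined_mask` (logical
#'   array), `refined_trace` and `seed_trace` (raw summed F(t), full
#'   recording length).
#' @export
roi_map <- function(movie, seed_mask, baseline_window = 16L,
                    r_threshold = 0.05, iterate = 1L) {
  stopifnot(inherits(movie, "volume_movie"), any(seed_mask))
  d <- dim(movie$voxels)
  if (!identical(dim(seed_mask), d[2:4])) stop("seed mask shape mismatch")
  flat <- matrix(movie$voxels, d[1], prod(d[2:4]))  # [t x voxel]
  vox_dff <- dff_matrix(t(flat), baseline_window)   # [voxel x t']
  mask <- as.vector(seed_mask)
  seed_trace <- NULL
  r <- NULL
  for (pass in seq_len(max(1L, iterate))) {
    trace <- rowSums(flat[, mask, drop = FALSE])  # sum of raw F over mask
    if (is.null(seed_trace)) seed_trace <- trace
    tr_dff <- as.vector(dff_matrix(matrix(trace, 1), baseline_window))
    if (stats::var(tr_dff) == 0) stop("degenerate seed trace")
    r <- row_pearson(vox_dff, tr_dff)
    mask <- !is.na(r) & r >= r_threshold
    if (!any(mask)) stop("refined ROI is empty at threshold ", r_threshold)
  }
  list(r = array(r, dim = d[2:4]),
       refined_mask = array(mask, dim = d[2:4]),
       refined_trace = rowSums(flat[, mask, drop = FALSE]),
       seed_trace = seed_trace)
}

#' Write a correlation map (or mask) as TIFF
#'
#' Pearson-r volumes are written as 32-bit float pages (one per z
#' plane), affinely mapped from `[-1, 1]` to the TIFF's `[0, 1]` sample
#' range (`(r + 1) / 2`; missing values map to 0.5, i.e. r = 0); masks
#' and label volumes are written as 8-bit, scaled by their maximum.
#'
#' @param map 3-D array `[z, y, x]`, numeric or logical.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  d <- dim(map)
  bits <- if (is.logical(map) || is.integer(map)) 8L else 32L
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- map[z, , ] * 1.0
    if (bits == 8L) {
      m[is.na(m)] <- 0
      m / max(1, max(m))
    } else {
      m[is.na(m)] <- 0
      (pmin(pmax(m, -1), 1) + 1) / 2
    }
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}
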