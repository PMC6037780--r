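#' Run configuration
#'
#' Bundles the numeric parameters of the classification pipeline. Defaults
#' follow the reference protocol: a 16-frame running baseline, 8-frame
#' windows rendered as 72x72 images, 25 Ward clusters, and Pearson-r
#' thresholds of 0.1 (display / dominant-pattern maps) and 0.05 (ROI
#' refinement).
#'
#' @param baseline_window Frames in the running baseline (default 16).
#' @param window_size Frames per analysis window (default 8).
#' @param image_side Side of the square window image in pixels (default 72).
#' @param clip_value Optional dF/F cap applied before normalization
#'   (default 2, the cap used for motoneuron drivers; set `NULL` to disable).
#' @param n_clusters Number of flat Ward clusters (default 25).
#' @param r_display_threshold Pearson r above which a voxel enters behavior
#'   and dominant-pattern maps (default 0.1).
#' @param r_roi_threshold Pearson r above which a voxel joins a refined ROI
#'   (default 0.05).
#' @param backbone Feature backbone kind, see [build_backbone()]
#'   (default "vgg16-random").
#' @param overlap_threshold Fraction of a ground-truth event that must be
#'   covered by a same-class prediction to count as a hit (default 0.5).
#' @param label_thresholds Cluster auto-labeling thresholds, see
#'   [label_thresholds()].
#' @param seed Integer seed for any stochastic component.
#'
#' @return A list of class `fm_config`.
#' @export
run_config <- function(baseline_window = 16L,
                       window_size = 8L,
                       image_side = 72L,
                       clip_value = 2,
                       n_clusters = 25L,
                       r_display_threshold = 0.1,
                       r_roi_threshold = 0.05,
                       backbone = "vgg16-random",
                       overlap_threshold = 0.5,
                       label_thresholds = NULL,
                       seed = 1L) {
  stopifnot(baseline_window >= 1, window_size >= 2, image_side >= window_size,
            n_clusters >= 1, r_display_threshold >= 0, r_roi_threshold >= 0,
            overlap_threshold > 0, overlap_threshold <= 1)
  if (!is.null(clip_value) && clip_value <= 0) stop("clip_value must be > 0")
  cfg <- list(
    baseline_window = as.integer(baseline_window),
    window_size = as.integer(window_size),
    image_side = as.integer(image_side),
    clip_value = clip_value,
    n_clusters = as.integer(n_clusters),
    r_display_threshold = r_display_threshold,
    r_roi_threshold = r_roi_threshold,
    backbone = backbone,
    overlap_threshold = overlap_threshold,
    label_thresholds = if (is.null(label_thresholds)) label_thresholds()
                       else label_thresholds,
    seed = as.integer(seed)
  )
  class(cfg) <- "fm_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param config An `fm_config` object.
#' @param path File path.
#' @return `read_config()` returns an `fm_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fm_config"))
  x <- unclass(config)
  x$clip_value <- if (is.null(x$clip_value)) "none" else x$clip_value
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$clip_value, "none")) x["clip_value"] <- list(NULL)
  do.call(run_config, x)
}
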