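#' Ward agglomerative clustering of window features
#'
#' Hierarchical agglomerative clustering with Ward's minimum-variance
#' criterion on Euclidean distances (via [stats::hclust()] with
#' `method = "ward.D2"`), cut into `n_clusters` flat clusters. Because the
#' tree is built once, the cut at `k` clusters is always a refinement of
#' the cut at `k - 1`.
#'
#' By default each feature vector is scaled to unit length first, so that
#' the linkage groups windows by activity *pattern* rather than by overall
#' activation magnitude; pooled convolutional features of these images are
#' otherwise dominated by total intensity, which mixes wave directions
#' within clusters. Quiescent windows keep a consistent feature direction
#' (the response to a near-constant image) and still form tight clusters.
#'
#' @param features Numeric matrix `[n_windows x n_features]` from
#'   [extract_features()].
#' @param n_clusters Number of flat clusters (default 25).
#' @param normalize Scale feature rows to unit Euclidean length before
#'   the linkage (default `TRUE`).
#' @return A `cluster_assignment`: list with `cluster` (integer vector in
#'   `1..n_clusters`, one per window), `tree` (the `hclust` object) and
#'   `n_clusters`.
#' @export
cluster_windows <- function(features, n_clusters = 25L, normalize = TRUE) {
  features <- as.matrix(features)
  k <- as.integer(n_clusters)
  if (k < 1) stop("n_clusters must be >= 1")
  if (k > nrow(features))
    stop("n_clusters exceeds the number of windows")
  if (normalize) {
    nrm <- sqrt(rowSums(features^2))
    features <- features / ifelse(nrm > 0, nrm, 1)
  }
  tree <- stats::hclust(stats::dist(features), method = "ward.D2")
  structure(list(cluster = unname(stats::cutree(tree, k = k)),
                 tree = tree, n_clusters = k),
            class = "cluster_assignment")
}

#' Per-cluster mean window images
#'
#' Averages the source `[n_segments x window_size]` window tensors within
#' each cluster; these mean images are what cluster labeling (automatic or
#' manual) inspects.
#'
#' @param assignment A `cluster_assignment` from [cluster_windows()].
#' @param stack The `window_stack` the features came from.
#' @return Named list of `[n_segments x window_size]` matrices, one per
#'   non-empty cluster id, each carrying a `coherence` attribute (energy
#'   of the mean relative to the members' mean energy: 1 for identical
#'   members, low for a mixture of distinct shapes); empty clusters are
#'   dropped with a warning.
#' @export
mean_cluster_windows <- function(assignment, stack) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(stack, "window_stack"))
  cl <- assignment$cluster
  if (length(cl) != dim(stack$windows)[3])
    stop("assignment does not cover the window stack")
  ids <- seq_len(assignment$n_clusters)
  empty <- setdiff(ids, unique(cl))
  if (length(empty))
    warning("empty cluster(s) excluded: ", paste(empty, collapse = ", "))
  keep <- setdiff(ids, empty)
  means <- lapply(keep, function(id) {
    w <- stack$windows[, , cl == id, drop = FALSE]
    m <- apply(w, c(1, 2), mean)
    # coherence: energy of the mean relative to the members' mean energy;
    # 1 for identical members, ~1/k when k distinct shapes are averaged
    attr(m, "coherence") <- sum(m^2) / max(mean(apply(w, 3, function(x)
      sum(x^2))), 1e-12)
    m
  })
  names(means) <- keep
  means
}

#' Auto-labeling thresholds
#'
#' Thresholds for mapping mean cluster windows to motor labels, calibrated
#' on the synthetic generator's default conditions:
#' `theta_qs` (mean normalized intensity below which a cluster is
#' quiescence), `theta_wave` (absolute center-of-mass slope, in segments
#' per frame, above which a cluster is a propagating wave),
#' `theta_at` / `theta_pt` (anterior / posterior mass fraction above which
#' a stationary cluster is a burst), `theta_r2` (minimum weighted R^2
#' of the center-of-mass regression for the wave call: a genuine wave
#' drifts linearly, whereas a burst hand-off between distant body regions
#' makes the center of mass jump and fits a line poorly) and
#' `theta_width` (minimum effective number of active segments — the
#' spatial participation ratio — for a burst call: a burst floods its
#' zone, while the narrow remnant of a wave entering or leaving the
#' recording sits in one or two segments and must not pass as a burst)
#' and `theta_burst` (minimum mean intensity for a burst call — bursts
#' are defined by *high* zone intensity, and the faint partial content of
#' windows at event borders must stay unlabeled).
#'
#' @param theta_qs,theta_wave,theta_at,theta_pt,theta_r2,theta_width
#'   Numeric thresholds.
#' @return A named list.
#' @export
label_thresholds <- function(theta_qs = 0.03, theta_wave = 0.35,
                             theta_at = 0.9, theta_pt = 0.9,
                             theta_r2 = 0.9, theta_width = 3,
                             theta_burst = 0.08,
                             theta_coherence_at = 0.8,
                             theta_coherence_pt = 0.55) {
  list(theta_qs = theta_qs, theta_wave = theta_wave,
       theta_at = theta_at, theta_pt = theta_pt, theta_r2 = theta_r2,
       theta_width = theta_width, theta_burst = theta_burst,
       theta_coherence_at = theta_coherence_at,
       theta_coherence_pt = theta_coherence_pt)
}

# anterior zone T2..A4 (segment indices 1..6), posterior zone A4..A7
# (6..9); A4 deliberately sits in both, ties resolved by the larger mass
ANTERIOR_ZONE <- 1:6
POSTERIOR_ZONE <- 6:9

window_diagnostics <- function(m) {
  mass_seg <- rowSums(m)
  total <- sum(mass_seg)
  ant <- if (total > 0) sum(mass_seg[ANTERIOR_ZONE]) / total else 0
  pos <- if (total > 0) sum(mass_seg[POSTERIOR_ZONE]) / total else 0
  mass_t <- colSums(m)
  ok <- mass_t > max(mass_t) * 0.05 & mass_t > 0
  slope <- 0
  r2 <- 0
  if (sum(ok) >= 2) {
    # mass-weighted regression: frames carrying little intensity say
    # little about where the activity sits
    com <- colSums(m * seq_len(nrow(m)))[ok] / mass_t[ok]
    t <- seq_len(ncol(m))[ok]
    w <- mass_t[ok]
    tw <- sum(w * t) / sum(w); cw <- sum(w * com) / sum(w)
    den <- sum(w * (t - tw)^2)
    ssc <- sum(w * (com - cw)^2)
    if (den > 0 && ssc > 0) {
      slope <- sum(w * (t - tw) * (com - cw)) / den
      r2 <- (sum(w * (t - tw) * (com - cw)))^2 / (den * ssc)
    }
  }
  # spatial participation ratio: effective number of active segments
  # (6 for a uniform anterior plateau, ~2 for a narrow traveling bump)
  width <- if (total > 0) sum(mass_seg)^2 / sum(mass_seg^2) else 0
  c(intensity = mean(m), anterior_frac = ant, posterior_frac = pos,
    com_slope = slope, com_r2 = r2, seg_width = width)
}

classify_mean_window <- function(m, th) {
  d <- window_diagnostics(m)
  coh <- attr(m, "coherence")
  d["coherence"] <- if (is.null(coh)) 1 else coh
  label <-
    if (d["intensity"] < th$theta_qs) "QS"
    else if (abs(d["com_slope"]) > th$theta_wave &&
             d["com_r2"] >= th$theta_r2) {
      if (d["com_slope"] < 0) "FW" else "BW"   # toward anterior = forward
    } else if (d["seg_width"] < th$theta_width ||
               d["intensity"] < th$theta_burst) "UL"
    else if (d["anterior_frac"] > th$theta_at &&
             d["coherence"] >= th$theta_coherence_at &&
             (d["posterior_frac"] <= th$theta_pt ||
              d["anterior_frac"] >= d["posterior_frac"])) "AT"
    else if (d["posterior_frac"] > th$theta_pt &&
             d["coherence"] >= th$theta_coherence_pt) "PT"
    else "UL"
  list(label = label, diagnostics = d)
}

#' Map clusters to motor labels from their mean windows
#'
#' Applies interpretable rules to each mean cluster window, mirroring how
#' an analyst reads the average images: near-zero intensity is quiescence
#' (QS); a steep intensity center-of-mass slope across time marks a
#' propagating wave, forward (FW) if the flow is posterior-to-anterior,
#' backward (BW) otherwise; stationary activity concentrated in the
#' anterior zone T2-A4 is an anterior burst (AT), in the posterior zone
#' A4-A7 a posterior burst (PT); anything else stays unlabeled (UL). Wave
#' rules take precedence over burst rules, the wave call additionally
#' requires the center-of-mass trajectory to be close to linear (see
#' [label_thresholds()]), and when both burst zones qualify the larger
#' mass wins.
#'
#' @param means Mean windows from [mean_cluster_windows()].
#' @param thresholds A [label_thresholds()] list.
#' @return A `cluster_label_map`: data frame with `cluster`, `label`, and
#'   diagnostic columns `intensity`, `anterior_frac`, `posterior_frac`,
#'   `com_slope`, `com_r2`, `seg_width`, `coherence`; the mean windows
#'   are kept in attribute `means`.
#' @export
auto_label_clusters <- function(means, thresholds = label_thresholds()) {
  res <- lapply(means, classify_mean_window, th = thresholds)
  map <- data.frame(cluster = as.integer(names(means)),
                    label = vapply(res, `[[`, "", "label"))
  diag <- t(vapply(res, function(r)
    r$diagnostics[c("intensity", "anterior_frac", "posterior_frac",
                    "com_slope", "com_r2", "seg_width", "coherence")],
    numeric(7)))
  map <- cbind(map, as.data.frame(diag))
  rownames(map) <- NULL
  attr(map, "means") <- means
  class(map) <- c("cluster_label_map", "data.frame")
  map
}

#' Override cluster labels manually
#'
#' Cluster labeling is ultimately a judgment call on the average images;
#' this applies analyst overrides on top of the automatic map.
#'
#' @param map A `cluster_label_map` from [auto_label_clusters()].
#' @param overrides Named character vector, names = cluster ids,
#'   values = motor labels (e.g. `c("3" = "BW")`).
#' @return The map with overridden labels.
#' @export
manual_label_clusters <- function(map, overrides = character()) {
  stopifnot(inherits(map, "cluster_label_map"))
  if (!length(overrides)) return(map)
  assert_label(overrides)
  ids <- as.integer(names(overrides))
  if (any(is.na(ids)) || !all(ids %in% map$cluster))
    stop("override references unknown cluster id(s)")
  map$label[match(ids, map$cluster)] <- unname(overrides)
  map
}

#' Refine unlabeled clusters by recursive subdivision
#'
#' A cluster that stays unlabeled (UL) at the flat cut is frequently a
#' *mixture* — e.g. wave windows lumped with junction windows — whose mean
#' image is uninformative mush rather than genuinely unclassifiable
#' content. This pass takes each UL cluster, bisects its members by a
#' local Ward linkage on their features, labels the sub-cluster means with
#' the same rules, and recurses while a part stays UL (up to `max_depth`,
#' never below `min_size` windows). Labels of non-UL clusters are
#' untouched; windows that remain UL at the bottom stay UL.
#'
#' @param assignment A `cluster_assignment` from [cluster_windows()].
#' @param map A `cluster_label_map` from [auto_label_clusters()].
#' @param features The feature matrix the clustering was built from.
#' @param stack The `window_stack`.
#' @param thresholds A [label_thresholds()] list.
#' @param max_depth Maximum recursion depth (default 4).
#' @param min_size Smallest sub-cluster worth keeping (default 6).
#' @param normalize Match the scale normalization used in
#'   [cluster_windows()] (default `TRUE`).
#' @return Character vector of refined per-window labels.
#' @export
refine_unlabeled <- function(assignment, map, features, stack,
                             thresholds = label_thresholds(),
                             max_depth = 4L, min_size = 6L,
                             normalize = TRUE) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(map, "cluster_label_map"))
  features <- as.matrix(features)
  if (normalize) {
    nrm <- sqrt(rowSums(features^2))
    features <- features / ifelse(nrm > 0, nrm, 1)
  }
  out <- window_labels(assignment, map)
  descend <- function(idx, depth) {
    w <- stack$windows[, , idx, drop = FALSE]
    m <- apply(w, c(1, 2), mean)
    attr(m, "coherence") <- sum(m^2) /
      max(mean(apply(w, 3, function(x) sum(x^2))), 1e-12)
    lab <- classify_mean_window(m, thresholds)$label
    if (lab != "UL") { out[idx] <<- lab; return(invisible()) }
    if (depth >= max_depth || length(idx) < 2L * min_size)
      return(invisible())
    part <- stats::cutree(
      stats::hclust(stats::dist(features[idx, , drop = FALSE]),
                    method = "ward.D2"), k = 2)
    for (p in 1:2) {
      sub <- idx[part == p]
      if (length(sub) >= min_size) descend(sub, depth + 1L)
    }
  }
  for (cl in map$cluster[map$label == "UL"]) {
    idx <- which(assignment$cluster == cl)
    if (length(idx) >= 2L * min_size) descend(idx, 0L)
  }
  out
}

#' Label every window through its cluster
#'
#' @param assignment A `cluster_assignment`.
#' @param map A `cluster_label_map` covering the assignment's clusters.
#' @return Character vector of motor labels, one per window.
#' @export
window_labels <- function(assignment, map) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(map, "cluster_label_map"))
  idx <- match(assignment$cluster, map$cluster)
  if (anyNA(idx)) stop("label map does not cover all clusters")
  map$label[idx]
}
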