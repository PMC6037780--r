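toy_movie <- function(n_t = 60, dims = c(2, 4, 4), f = NULL, seed = 40) {
  set.seed(seed)
  vox <- array(runif(n_t * prod(dims), 80, 120), dim = c(n_t, dims))
  volume_movie(vox, 0.3)
}

test_that("voxel dF/F matches the scalar trace transform", {
  mov <- toy_movie()
  vd <- voxel_dff(mov, 16)
  expect_equal(dim(vd$values), c(44, 2, 4, 4))
  # spot-check voxels against compute_dff on a single-ROI equivalent
  for (idx in list(c(1, 2, 3), c(2, 4, 1), c(1, 1, 4))) {
    tr <- mov$voxels[, idx[1], idx[2], idx[3]]
    v18 <- matrix(rep(tr, each = 18), 18)
    oracle <- compute_dff(make_traces(v18), 16)$values[1, ]
    expect_equal(vd$values[, idx[1], idx[2], idx[3]], oracle)
  }
  # constant movie gives all-zero dF/F
  flat <- volume_movie(array(100, dim = c(40, 1, 3, 3)), 0.3)
  expect_true(all(voxel_dff(flat, 16)$values == 0))
})

test_that("behavior maps correlate voxels against the label indicator", {
  n_t <- 40
  ind <- rep(c(0, 1), length.out = n_t)
  vox <- array(0, dim = c(n_t, 1, 2, 2))
  vox[, 1, 1, 1] <- ind          # equals the indicator -> r = 1
  vox[, 1, 1, 2] <- 1 - ind      # anti-phase -> r = -1
  vox[, 1, 2, 1] <- 0.5          # constant -> NA
  set.seed(41)
  vox[, 1, 2, 2] <- rnorm(n_t)
  vd <- structure(list(values = vox, first_valid_frame = 16L,
                       frame_interval_s = 0.3), class = "voxel_dff")
  series <- structure(ifelse(ind == 1, "BW", "QS"),
                      first_valid_frame = 16L, class = "label_series")
  r <- behavior_map(vd, series, "BW")
  expect_equal(r[1, 1, 1], 1)
  expect_equal(r[1, 1, 2], -1)
  expect_true(is.na(r[1, 2, 1]))
  # covariance-formula oracle on the random voxel
  x <- vox[, 1, 2, 2]
  oracle <- sum((x - mean(x)) * (ind - mean(ind))) /
    sqrt(sum((x - mean(x))^2) * sum((ind - mean(ind))^2))
  expect_equal(r[1, 2, 2], oracle)
  expect_warning(behavior_map(vd, structure(rep("QS", n_t),
                                            class = "label_series"), "BW"),
                 "constant")
})

test_that("behavior maps are invariant to positive affine rescaling", {
  set.seed(42)
  vox <- array(rexp(30 * 8), dim = c(30, 2, 2, 2))
  vd <- structure(list(values = vox, first_valid_frame = 16L,
                       frame_interval_s = 0.3), class = "voxel_dff")
  series <- structure(sample(c("FW", "QS"), 30, replace = TRUE),
                      class = "label_series")
  r1 <- behavior_map(vd, series, "FW")
  vd2 <- vd; vd2$values <- 3.7 * vd$values + 11
  expect_equal(behavior_map(vd2, series, "FW"), r1, tolerance = 1e-12)
})

test_that("dominant map takes the argmax above threshold with fixed ties", {
  shape <- c(1, 2, 2)
  m <- function(v) array(v, dim = shape)
  maps <- list(AT = m(c(0.5, 0.05, 0.3, NA)),
               BW = m(c(0.2, 0.04, 0.3, 0.2)),
               FW = m(c(0.1, 0.06, 0.05, NA)),
               PT = m(c(0.0, 0.01, 0.01, 0.1)))
  dom <- dominant_map(maps, threshold = 0.1)
  expect_equal(dom[1, 1, 1], 1)          # AT wins
  expect_true(is.na(dom[1, 2, 1]))       # all below threshold
  expect_equal(dom[1, 1, 2], 1)          # AT/BW tie -> first in order
  expect_equal(dom[1, 2, 2], 2)          # NA treated as absent
  expect_equal(attr(dom, "patterns"), c("AT", "BW", "FW", "PT"))
  # idempotent under map duplication
  expect_equal(as.vector(dominant_map(c(maps, maps[1]), 0.1)[1, , ]),
               as.vector(dom[1, , ]))
  expect_error(dominant_map(list(AT = m(1:4), BW = array(1, c(1, 1, 4)))),
               "mismatch")
})

test_that("seed-ROI mapping recovers a planted synchronous unit", {
  set.seed(43)
  n_t <- 80
  dims <- c(2, 4, 4)
  sig <- 100 + 30 * pmax(0, sin(seq_len(n_t) / 4))
  vox <- array(runif(n_t * prod(dims), 95, 105), dim = c(n_t, dims))
  unit <- cbind(z = c(1, 1, 2), y = c(2, 2, 3), x = c(2, 3, 2))
  for (i in seq_len(nrow(unit)))
    vox[, unit[i, 1], unit[i, 2], unit[i, 3]] <- sig
  mov <- volume_movie(vox, 0.3)
  seed_mask <- array(FALSE, dims); seed_mask[1, 2, 2] <- TRUE
  res <- roi_map(mov, seed_mask, 16, r_threshold = 0.05)
  # the seed voxel correlates perfectly with itself
  expect_equal(res$r[1, 2, 2], 1, tolerance = 1e-9)
  for (i in seq_len(nrow(unit)))
    expect_true(res$refined_mask[unit[i, 1], unit[i, 2], unit[i, 3]])
  # refined trace equals the loop-oracle sum over the mask
  oracle <- numeric(n_t)
  for (t in seq_len(n_t)) {
    acc <- 0
    for (z in 1:2) for (y in 1:4) for (x in 1:4)
      if (res$refined_mask[z, y, x]) acc <- acc + vox[t, z, y, x]
    oracle[t] <- acc
  }
  expect_equal(res$refined_trace, oracle)
  expect_error(roi_map(mov, array(FALSE, dims)), "any")
})
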