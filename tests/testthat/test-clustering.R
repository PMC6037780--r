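test_that("Ward clustering separates tight blobs and merges nearest pairs first", {
  set.seed(10)
  blob1 <- matrix(rnorm(40 * 5, 0, 0.1), 40, 5)
  blob2 <- matrix(rnorm(40 * 5, 4, 0.1), 40, 5)
  asg <- cluster_windows(rbind(blob1, blob2), 2, normalize = FALSE)
  expect_length(asg$cluster, 80)
  expect_length(unique(asg$cluster[1:40]), 1)
  expect_length(unique(asg$cluster[41:80]), 1)
  expect_false(asg$cluster[1] == asg$cluster[41])

  # 1-D points {0, 1, 10, 11}: Ward's increment for merging {0},{1} is
  # 0.5, for {10},{11} is 0.5, for any cross pair >= 40.5, so the first
  # two merges join the near pairs
  asg1 <- cluster_windows(matrix(c(0, 1, 10, 11), 4, 1), 2,
                          normalize = FALSE)
  expect_equal(asg1$cluster[1], asg1$cluster[2])
  expect_equal(asg1$cluster[3], asg1$cluster[4])
  expect_false(asg1$cluster[1] == asg1$cluster[3])
  merges <- asg1$tree$merge
  expect_setequal(lapply(list(-merges[1, ], -merges[2, ]),
                         function(x) sort(as.numeric(x))),
                  list(c(1, 2), c(3, 4)))

  expect_error(cluster_windows(blob1, 0), ">= 1")
  expect_error(cluster_windows(blob1, 41), "exceeds")
})

test_that("a cut at k refines the cut at k - 1", {
  set.seed(11)
  f <- matrix(rnorm(60 * 8), 60, 8)
  for (k in 3:8) {
    a <- cluster_windows(f, k, normalize = FALSE)$cluster
    b <- cluster_windows(f, k - 1, normalize = FALSE)$cluster
    # every cluster at k sits wholly inside one cluster at k - 1
    expect_true(all(tapply(b, a, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster labels are invariant to global feature rescaling", {
  set.seed(12)
  wins <- c(lapply(1:6, function(i) wave_window("fw")),
            lapply(1:6, function(i) wave_window("bw")),
            lapply(1:6, function(i) burst_window(1:6)))
  st <- stack_from_windows(wins)
  f <- extract_features(st, build_backbone("blockmean"))
  a1 <- cluster_windows(f, 3)
  a2 <- cluster_windows(f * 37.5, 3)
  m1 <- auto_label_clusters(mean_cluster_windows(a1, st))
  m2 <- auto_label_clusters(mean_cluster_windows(a2, st))
  expect_identical(window_labels(a1, m1), window_labels(a2, m2))
})

test_that("mean cluster windows equal the elementwise loop oracle", {
  set.seed(13)
  wins <- lapply(1:7, function(i) matrix(runif(72), 9, 8))
  st <- stack_from_windows(wins)
  asg <- structure(list(cluster = c(1L, 2L, 1L, 2L, 2L, 1L, 1L),
                        tree = NULL, n_clusters = 2L),
                   class = "cluster_assignment")
  means <- mean_cluster_windows(asg, st)
  oracle <- matrix(0, 9, 8)
  idx <- c(1, 3, 6, 7)
  for (s in 1:9) for (t in 1:8)
    oracle[s, t] <- mean(vapply(idx, function(i) wins[[i]][s, t], 0))
  expect_equal(means[["1"]], oracle, ignore_attr = TRUE)
  # coherence of identical members is 1, of mixtures below 1
  expect_lt(attr(means[["1"]], "coherence"), 1)
  # singleton-equivalent: identical windows give that window back
  st2 <- stack_from_windows(list(wins[[2]], wins[[2]]))
  asg2 <- structure(list(cluster = c(1L, 1L), tree = NULL, n_clusters = 2L),
                    class = "cluster_assignment")
  expect_warning(m2 <- mean_cluster_windows(asg2, st2), "empty cluster")
  expect_equal(m2[["1"]], wins[[2]], ignore_attr = TRUE)
  expect_equal(attr(m2[["1"]], "coherence"), 1)
})

test_that("auto-labeling recognizes the canonical pattern archetypes", {
  th <- label_thresholds()
  qs <- auto_label_clusters(list(`1` = matrix(0, 9, 8)), th)
  expect_equal(qs$label, "QS")

  fw <- auto_label_clusters(list(`1` = wave_window("fw")), th)
  expect_equal(fw$label, "FW")
  expect_lt(fw$com_slope, 0)  # flow toward anterior

  bw <- auto_label_clusters(list(`1` = wave_window("bw")), th)
  expect_equal(bw$label, "BW")
  expect_gt(bw$com_slope, 0)

  at <- auto_label_clusters(list(`1` = burst_window(1:3)), th)
  pt <- auto_label_clusters(list(`1` = burst_window(7:9)), th)
  expect_equal(at$label, "AT")
  expect_equal(pt$label, "PT")
  # mass fractions agree with a manual sum over the zone segments
  m <- burst_window(7:9)
  expect_equal(pt$posterior_frac,
               sum(m[6:9, ]) / sum(m))
  expect_equal(pt$anterior_frac, sum(m[1:6, ]) / sum(m))
})

test_that("manual overrides replace auto labels and are validated", {
  means <- list(`1` = matrix(0, 9, 8), `2` = wave_window("fw"))
  map <- auto_label_clusters(means)
  expect_identical(manual_label_clusters(map), map)
  map2 <- manual_label_clusters(map, c(`2` = "BW"))
  expect_equal(map2$label[map2$cluster == 2], "BW")
  expect_equal(map2$label[map2$cluster == 1], map$label[map$cluster == 1])
  expect_error(manual_label_clusters(map, c(`9` = "BW")), "unknown cluster")
  expect_error(manual_label_clusters(map, c(`1` = "XX")), "unknown motor label")
})
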