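test_that("event frequency is count per minute and scales with duration", {
  ev <- event_table(class = rep(c("FW", "QS"), 6),
                    start_frame = seq(0L, 110L, 10L),
                    end_frame = seq(10L, 120L, 10L),
                    duration_s = rep(3, 12))
  f <- event_frequency(ev, 120)
  expect_equal(unname(f["FW"]), 3)   # 6 events in 2 min
  expect_equal(unname(f["AT"]), 0)
  expect_equal(event_frequency(ev, 240), f / 2)
  expect_equal(unname(event_frequency(event_table(), 60)), rep(0, 4))
})

test_that("event intensity equals the double-loop maximum oracle", {
  set.seed(30)
  v <- matrix(runif(9 * 40), 9, 40)
  n9 <- norm9_from_matrix(v, first_valid_frame = 0L)
  ev <- event_table("BW", 12L, 25L, 3.9)
  m <- -Inf
  for (r in 1:9) for (f in 13:25) m <- max(m, v[r, f])
  expect_equal(event_intensity(ev, n9), m)
  expect_error(event_intensity(event_table("BW", 30L, 45L, 4.5), n9),
               "outside")
})

test_that("asymmetry index follows its definition and symmetries", {
  v <- matrix(0, 18, 3)
  v[5, 1] <- 0.2   # A1 L
  v[6, 1] <- 0.6   # A1 R
  v[1, 2] <- 0.5; v[2, 2] <- 0.5  # symmetric frame
  n18 <- norm18_from_matrix(v, first_valid_frame = 0L)
  ai <- asymmetry_index(n18)
  expect_equal(ai[1], abs(0.2 - 0.6) / 0.6)
  expect_equal(ai[2], 0)
  expect_true(is.na(ai[3]))  # silent frame undefined

  # swapping L and R globally leaves the index unchanged
  swap <- v[rep(1:9 * 2, each = 2) - c(0, 1), ]
  expect_equal(asymmetry_index(norm18_from_matrix(swap,
                                                  first_valid_frame = 0L)),
               ai)
  # fully one-sided activity gives 1
  one <- matrix(0, 18, 1); one[3, 1] <- 0.7
  expect_equal(asymmetry_index(norm18_from_matrix(one,
                                                  first_valid_frame = 0L)), 1)
})

test_that("transition matrices count consecutive pairs after filtering", {
  mk <- function(classes) {
    n <- length(classes)
    event_table(class = classes, start_frame = seq_len(n) * 10L,
                end_frame = seq_len(n) * 10L + 5L, duration_s = 1.5)
  }
  # dropping AT concatenates the BW events
  tm <- transition_matrix(mk(c("BW", "AT", "BW", "AT")),
                          states = c("BW", "FW"))
  expect_equal(tm$probabilities["BW", "BW"], 1)
  expect_equal(tm$undefined_rows, "FW")

  tm2 <- transition_matrix(mk(c("FW", "PT", "FW", "PT")))
  expect_equal(tm2$probabilities["FW", "PT"], 1)
  expect_equal(tm2$probabilities["PT", "FW"], 1)

  set.seed(31)
  classes <- sample(c("AT", "BW", "FW", "PT", "QS", "UL"), 20, replace = TRUE)
  tm3 <- transition_matrix(mk(classes))
  kept <- classes[classes != "UL"]
  oracle <- matrix(0, 5, 5, dimnames = dimnames(tm3$counts))
  for (i in seq_len(length(kept) - 1))
    oracle[kept[i], kept[i + 1]] <- oracle[kept[i], kept[i + 1]] + 1
  expect_equal(unclass(tm3$counts), unclass(oracle), ignore_attr = TRUE)
  rs <- rowSums(tm3$counts)
  ok <- rs > 0
  expect_equal(rowSums(tm3$probabilities)[ok], rep(1, sum(ok)),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_warning(transition_matrix(mk("FW")), "fewer than 2")
})

test_that("transition probabilities recover a known Markov chain within 3 SE", {
  sim <- sim_config(n_frames = 60000L)
  truth <- simulate_events(sim, seed = 5)
  truth <- truth[-1, ]  # drop the deterministic lead-in
  expect_gt(nrow(truth), 500)
  tm <- transition_matrix(truth)
  gen <- default_transitions()
  n_from <- rowSums(tm$counts)
  for (a in tm$states) for (b in tm$states) {
    p <- gen[a, b]
    if (n_from[a] == 0) next
    se <- sqrt(p * (1 - p) / n_from[a])
    expect_lt(abs(tm$probabilities[a, b] - p), max(3 * se, 1e-9),
              label = sprintf("transition %s->%s", a, b))
  }
})

test_that("end-aligned averages equal the per-frame loop oracle", {
  set.seed(32)
  v <- matrix(runif(9 * 120), 9, 120)
  n9 <- norm9_from_matrix(v, first_valid_frame = 0L, frame_interval_s = 1)
  ev <- event_table(class = rep("FW", 3),
                    start_frame = c(10L, 48L, 80L),
                    end_frame = c(20L, 60L, 95L),
                    duration_s = c(10, 12, 15))
  prof <- aligned_average(ev, n9, window_before_s = 5, window_after_s = 3,
                          classes = "FW")
  expect_equal(prof$FW$n_events, 3)
  oracle <- matrix(0, 9, 8)
  for (e in c(20, 60, 95)) oracle <- oracle + v[, (e - 4):(e + 3)]
  expect_equal(prof$FW$profile, oracle / 3)
  expect_equal(prof$FW$duration_mean_s, mean(c(10, 12, 15)))
  expect_equal(prof$FW$duration_sd_s, sd(c(10, 12, 15)))

  # single event: profile is that event's segment; truncated events drop
  ev2 <- event_table(class = c("BW", "BW"), start_frame = c(0L, 50L),
                     end_frame = c(3L, 60L), duration_s = c(3, 10))
  expect_warning(p1 <- aligned_average(ev2[1, ], n9, 5, 3, classes = "BW"),
                 "no complete")
  p2 <- aligned_average(ev2, n9, 5, 3, classes = "BW")
  expect_equal(p2$BW$n_events, 1)
  expect_equal(p2$BW$profile, v[, 56:63])

  # two identical events give that segment exactly
  ev3 <- event_table(class = c("AT", "QS", "AT"),
                     start_frame = c(10L, 20L, 30L),
                     end_frame = c(20L, 30L, 40L), duration_s = 10)
  v2 <- v; v2[, 31:48] <- v2[, 11:28]
  n9b <- norm9_from_matrix(v2, first_valid_frame = 0L, frame_interval_s = 1)
  p3 <- aligned_average(ev3, n9b, 5, 3, classes = "AT")
  expect_equal(p3$AT$profile, v2[, 16:23])
})
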