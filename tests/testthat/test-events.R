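test_that("window labels expand to a compensated frame series", {
  labs <- rep("QS", 2024)
  series <- window_labels_to_series(labs, 4:2027, 2032)
  expect_length(series, 2032)
  expect_true(all(series == "QS"))

  # hand simulation at T = 12: centers 4..7, padding copies the ends
  labs4 <- c("FW", "FW", "BW", "QS")
  s <- window_labels_to_series(labs4, 4:7, 12)
  expect_equal(as.character(s),
               c("FW", "FW", "FW", "FW", "FW", "FW", "BW", "QS",
                 "QS", "QS", "QS", "QS"))
  expect_error(window_labels_to_series(labs4, 4:7, 13), "inconsistent")
  expect_error(window_labels_to_series(labs4, c(4, 5, 7, 8), 12),
               "consecutive")
})

test_that("run-length event extraction matches the oracle on random series", {
  s <- structure(c("FW", "FW", "FW", "QS", "QS", "BW"),
                 first_valid_frame = 16L, class = "label_series")
  ev <- extract_events(s, 0.3)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$class, c("FW", "QS", "BW"))
  expect_equal(ev$start_frame, c(16L, 19L, 21L))
  expect_equal(ev$end_frame, c(19L, 21L, 22L))
  expect_equal(ev$duration_s, c(0.9, 0.6, 0.3))

  uni <- extract_events(rep("AT", 50), 0.1)
  expect_equal(nrow(uni), 1)
  expect_equal(uni$duration_s, 5)

  set.seed(21)
  for (i in 1:10) {
    s <- sample(MOTOR_LABELS, 60, replace = TRUE)
    ev <- extract_events(s, 0.3)
    expect_equal(sum(ev$end_frame - ev$start_frame), 60)
    expect_true(all(ev$class[-1] != head(ev$class, -1)))
    # round trip back to the series
    expect_equal(as.character(events_to_series(ev, 60)), s)
  }
})

test_that("event intensity and asymmetry columns come from the traces", {
  v9 <- matrix(0, 9, 20); v9[3, 8] <- 0.9; v9[5, 15] <- 0.4
  n9 <- norm9_from_matrix(v9, first_valid_frame = 0L)
  v18 <- matrix(0, 18, 20); v18[5, 1:10] <- 0.8  # A1 left only
  n18 <- norm18_from_matrix(v18, first_valid_frame = 0L)
  s <- structure(rep(c("FW", "QS"), each = 10), first_valid_frame = 0L,
                 class = "label_series")
  ev <- extract_events(s, 0.3, n9, n18)
  expect_equal(ev$intensity, c(0.9, 0.4))
  expect_equal(ev$mean_asymmetry, c(1, NaN))

  one <- ev[1, , drop = FALSE]
  expect_equal(event_intensity(one, n9), 0.9)
})

test_that("evaluation scores hits and false alarms per class", {
  truth <- event_table(class = c("FW", "QS", "BW", "QS", "AT"),
                       start_frame = c(0L, 10L, 20L, 30L, 40L),
                       end_frame = c(10L, 20L, 30L, 40L, 50L),
                       duration_s = rep(3, 5))
  expect_identical_rates <- function(res, cl, hr, far) {
    row <- res[res$class == cl, ]
    expect_equal(row$hit_rate, hr)
    expect_equal(row$false_alarm_rate, far)
  }
  perfect <- evaluate_events(truth, truth)
  for (cl in c("FW", "BW", "AT")) expect_identical_rates(perfect, cl, 1, 0)
  expect_true(is.na(perfect$hit_rate[perfect$class == "PT"]))

  # shift by more than any event length: nothing overlaps
  shifted <- truth
  shifted$start_frame <- shifted$start_frame + 60L
  shifted$end_frame <- shifted$end_frame + 60L
  none <- evaluate_events(shifted, truth)
  for (cl in c("FW", "BW", "AT")) expect_identical_rates(none, cl, 0, 1)
})

test_that("evaluation matches a brute-force overlap oracle on a toy case", {
  truth <- event_table(class = c("FW", "FW", "BW"),
                       start_frame = c(0L, 20L, 40L),
                       end_frame = c(10L, 30L, 50L),
                       duration_s = rep(3, 3))
  pred <- event_table(class = c("FW", "FW", "BW", "BW"),
                      start_frame = c(4L, 26L, 41L, 70L),
                      end_frame = c(12L, 29L, 49L, 75L),
                      duration_s = c(2.4, 0.9, 2.4, 1.5))
  res <- evaluate_events(pred, truth, overlap_threshold = 0.5)
  # brute force: truth FW#1 overlapped 6/10 by pred#1 (hit), truth FW#2
  # overlapped 3/10 (miss), truth BW overlapped 8/10 (hit); pred BW#2
  # overlaps no truth BW (false alarm)
  expect_equal(res$hits[res$class == "FW"], 1L)
  expect_equal(res$hits[res$class == "BW"], 1L)
  expect_equal(res$false_alarms[res$class == "FW"], 0L)
  expect_equal(res$false_alarms[res$class == "BW"], 1L)
  expect_equal(res$hit_rate[res$class == "FW"], 0.5)
  expect_equal(res$false_alarm_rate[res$class == "BW"], 0.5)

  # permutation equivariance: relabeling classes permutes rows only
  swap <- function(x) ifelse(x == "FW", "BW", ifelse(x == "BW", "FW", x))
  truth2 <- truth; truth2$class <- swap(truth2$class)
  pred2 <- pred; pred2$class <- swap(pred2$class)
  res2 <- evaluate_events(pred2, truth2)
  expect_equal(res2[res2$class == "BW", -1],
               res[res$class == "FW", -1], ignore_attr = TRUE)
  expect_equal(res2[res2$class == "FW", -1],
               res[res$class == "BW", -1], ignore_attr = TRUE)
})
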