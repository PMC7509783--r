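test_that("beats_to_rr differences beat times and keeps onsets", {
  b <- beat_series(c(0, 800, 1600, 2410))
  rr <- beats_to_rr(b)
  expect_equal(rr$rr, c(800, 800, 810))
  expect_equal(rr$start_times, c(0, 800, 1600))

  expect_equal(beats_to_rr(beat_series(c(0, 1000)))$rr, 1000)
  expect_error(beats_to_rr(beat_series(5000)), "at least 2 beats")
  expect_error(beat_series(c(0, 800, 750)), "not strictly increasing at index 3")
})

test_that("beat times round-trip through the RR series exactly", {
  set.seed(41)
  for (i in 1:10) {
    times <- cumsum(runif(200, 500, 1200))
    rr <- beats_to_rr(beat_series(times))
    expect_equal(times[1] + cumsum(rr$rr), times[-1])
    expect_equal(rr$start_times[1] + cumsum(rr$rr[-length(rr$rr)]),
                 rr$start_times[-1])
  }
})

test_that("ectopic beats are respaced by linear interpolation", {
  b <- beat_series(c(0, 800, 1200, 2400), c("N", "N", "V", "N"))
  out <- suppressWarnings(replace_ectopic(b))  # 1 of 4 beats exceeds the 5% load
  expect_equal(out$times, c(0, 800, 1600, 2400))
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_true(all(out$labels == "N"))

  # a run of two between anchors splits the gap into equal thirds
  b2 <- beat_series(c(0, 900, 1100, 2400), c("N", "V", "V", "N"))
  out2 <- suppressWarnings(replace_ectopic(b2))  # 50% non-normal warns
  expect_equal(out2$times, c(0, 800, 1600, 2400))
  expect_equal(attr(out2, "n_replaced"), 2L)

  # identity on an all-normal series
  b3 <- beat_series(c(0, 700, 1500))
  expect_equal(replace_ectopic(b3)$times, b3$times)
  expect_equal(attr(replace_ectopic(b3), "n_replaced"), 0L)
})

test_that("ectopic replacement preserves endpoints and beat count", {
  set.seed(42)
  for (i in 1:10) {
    n <- 120
    times <- cumsum(runif(n, 600, 1000))
    labels <- rep("N", n)
    labels[sample(2:(n - 1), 4)] <- sample(c("V", "S", "A"), 4, replace = TRUE)
    out <- replace_ectopic(beat_series(times, labels))
    expect_equal(length(out$times), n)
    expect_equal(out$times[c(1, n)], times[c(1, n)])
    expect_true(all(diff(out$times) > 0))
  }
})

test_that("ectopic replacement warns on high correction load and trims edges", {
  n <- 30
  times <- cumsum(rep(800, n))
  labels <- rep("N", n); labels[seq(2, 28, by = 3)] <- "V"
  expect_warning(replace_ectopic(beat_series(times, labels)), "non-normal beats")

  labels2 <- rep("N", 5); labels2[1] <- "V"
  b_edge <- beat_series(cumsum(rep(800, 5)), labels2)
  w <- capture_warnings(out <- replace_ectopic(b_edge))
  expect_true(any(grepl("trimmed", w)))
  expect_equal(length(out$times), 4L)
  expect_equal(attr(out, "n_trimmed"), 1L)
})

test_that("window extraction selects onsets in the half-open span", {
  beats <- beat_series(seq(0, 310000, by = 1000))
  rr <- beats_to_rr(beats)
  win <- extract_window(rr, analysis_window(300000, "T1"))
  expect_equal(length(win$rr), 300L)
  expect_equal(win$window_label, "T1")
  expect_true(sum(win$rr) <= 300000)

  rr750 <- beats_to_rr(beat_series(seq(0, 310000, by = 750)))
  expect_equal(length(extract_window(rr750, analysis_window(300000, "T2"))$rr),
               400L)

  # an interval starting exactly at the marker belongs to the next window
  expect_false(300000 %in% win$start_times)
  expect_error(analysis_window(100000, "T1"), "before the recording")
  # marker past the recording end: empty selection
  expect_error(extract_window(rr, analysis_window(900000, "T3")),
               "no intervals")
})

test_that("successive differences reconstruct the parent series", {
  rr <- rr_series(c(800, 810, 805))
  d <- rr_diff(rr)
  expect_equal(d$drr, c(10, -5))
  expect_equal(rr$rr[1] + cumsum(d$drr), rr$rr[-1])
  expect_equal(rr_diff(rr_series(rep(700, 5)))$drr, rep(0, 4))
  expect_equal(rr_diff(rr_series(c(616, 672)))$drr, 56)
  expect_error(rr_diff(rr_series(800)), "at least 2")
})

test_that("tachogram, beat and marker files round-trip", {
  rr <- rr_series(c(800.5, 810.25, 790))
  f <- withr::local_tempfile(fileext = ".txt")
  write_tachogram(rr, f)
  expect_equal(read_tachogram(f)$rr, rr$rr)

  # seconds unit and comment handling
  writeLines(c("# comment", "0.8", "", "0.75"), f)
  expect_equal(read_tachogram(f, unit = "s")$rr, c(800, 750))

  b <- beat_series(c(0, 800, 1650), c("N", "V", "N"))
  fb <- withr::local_tempfile(fileext = ".csv")
  write_beats(b, fb)
  b2 <- read_beats(fb, subject_id = "S01")
  expect_equal(b2$times, b$times)
  expect_equal(b2$labels, b$labels)
  expect_equal(b2$subject_id, "S01")

  mk <- data.frame(label = c("T2", "T1"), time_ms = c(600000, 300000))
  fm <- withr::local_tempfile(fileext = ".csv")
  write_markers(mk, fm)
  expect_equal(read_markers(fm)$label, c("T1", "T2"))  # reordered T1..T9
})

test_that("corrupt input files fail with a located error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("800", "oops", "750"), f)
  expect_error(read_tachogram(f), "data line 2")

  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,label", "0,N", "800,N", "750,N"), fb)
  expect_error(read_beats(fb), "non-increasing")
})
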