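test_that("a noise-free metronome produces exactly one beat per second", {
  spec <- period_spec("T1", base_rr = 1000, drift = 0, a_lf = 0, a_hf = 0,
                      noise_sd = 0)
  b <- generate_window(spec, seed = 1)
  expect_equal(diff(b$times), rep(1000, length(b$times) - 1))
  rr <- beats_to_rr(b)
  win <- extract_window(rr, analysis_window(300000, "T1"))
  expect_equal(length(win$rr), 300L)
})

test_that("window generation is reproducible from its seed", {
  spec <- default_period_specs()$T3
  a <- generate_window(spec, seed = 7)
  b <- generate_window(spec, seed = 7)
  expect_identical(a$times, b$times)
  expect_false(identical(a$times, generate_window(spec, seed = 8)$times))
})

test_that("a pure HF modulation shows up almost entirely in the HF band", {
  spec <- period_spec("T1", base_rr = 800, a_lf = 0, a_hf = 20, noise_sd = 0)
  rr <- beats_to_rr(generate_window(spec, seed = 2))
  expect_gt(spectral_analysis(rr)$hf_pct, 90)
})

test_that("generated LF/HF amplitude ratios map to measured band powers", {
  set.seed(61)
  for (amps in list(c(30, 15), c(15, 30), c(25, 25))) {
    spec <- period_spec("T1", base_rr = 800, a_lf = amps[1], a_hf = amps[2],
                        noise_sd = 0)
    ratio <- spectral_analysis(beats_to_rr(generate_window(spec)))$lf_hf_ratio
    expect_equal(ratio, (amps[1] / amps[2])^2, tolerance = 0.15)
  }
})

test_that("invalid period specifications are rejected", {
  expect_error(period_spec("T1", base_rr = -5), "positive")
  expect_error(period_spec("T1", 800, f_lf = 0.2), "LF band")
  expect_error(period_spec("T1", 800, f_hf = 0.1), "HF band")
  expect_error(period_spec("T1", 800, a_lf = -1), ">= 0")
  # amplitudes exceeding the baseline drive RR non-positive
  bad <- period_spec("T1", base_rr = 100, a_lf = 300, noise_sd = 0)
  expect_error(generate_window(bad, seed = 1), "non-positive")
})

test_that("cohort generation is byte-identical under a fixed master seed", {
  spec <- cohort_spec(n_subjects = 3, n_female = 2, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(spec), d1)
  write_cohort(generate_cohort(spec), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)  # beats+tachogram per subject, markers, vas, gender
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("the default cohort reproduces the stress ordering of mean RR", {
  co <- generate_cohort(cohort_spec(n_subjects = 8, n_female = 4, seed = 12))
  expect_equal(length(co$subjects), 8L)
  med <- sapply(c("T1", "T4", "T9"), function(lab) {
    median(sapply(co$subjects, function(s) {
      rr <- beats_to_rr(replace_ectopic(s$beats))
      w <- extract_window(rr, analysis_window(
        s$markers$time_ms[s$markers$label == lab], lab))
      mean(w$rr)
    }))
  })
  expect_lt(med["T4"], med["T1"])
  expect_lt(med["T4"], med["T9"])
})

test_that("VAS missingness feeds Skillings-Mack while Friedman drops rows", {
  periods <- default_period_specs()
  for (i in seq_along(periods)) periods[[i]]$vas_missing_prob <- 0.25
  co <- generate_cohort(cohort_spec(n_subjects = 10, n_female = 5,
                                    periods = periods, seed = 13))
  vm <- matrix(co$vas$score, nrow = 10, byrow = TRUE,
               dimnames = list(unique(co$vas$subject), paste0("T", 1:9)))
  expect_true(anyNA(vm))
  sm <- skillings_mack(vm)
  expect_gt(sm$n, sum(complete.cases(vm)))
  expect_true(sm$p.value >= 0 && sm$p.value <= 1)
})

test_that("injected ectopic beats exercise the correction stage", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, n_female = 1,
                                    ectopic_prob = 0.01, seed = 14))
  b <- co$subjects[[1]]$beats
  expect_gt(sum(b$labels == "V"), 0)
  fixed <- replace_ectopic(b)
  expect_gt(attr(fixed, "n_replaced"), 0)
  expect_true(all(fixed$labels == "N"))
})

test_that("cohort specification is validated", {
  expect_error(cohort_spec(n_subjects = 1), ">= 2 subjects")
  expect_error(cohort_spec(n_subjects = 8), "n_female")
  expect_error(cohort_spec(periods = default_period_specs()[1:3]), "nine")
})
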