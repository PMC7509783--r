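# Synthetic TSST-like cohort generator. Emulates what the analysis chain
# needs from a real recording session: per-period RR baseline shifts
# (rest ~855 ms -> stress ~616 ms -> recovery ~885 ms), LF (~0.1 Hz) and HF
# (~0.25 Hz) modulation, within-window drift (nonstationarity), occasional
# ectopic beats, and VAS scores with missingness.

#' Specification of one 5-min analysis period
#'
#' The instantaneous tachogram of a period is
#' `r(t) = base_rr + drift*(t/T - 1/2) + a_lf*sin(2 pi f_lf t + phi1) +
#' a_hf*sin(2 pi f_hf t + phi2) + noise`, so `base_rr` is the period's mean
#' RR and `drift` the total linear change across the window.
#'
#' @param label period tag `"T1"`..`"T9"`.
#' @param base_rr mean RR of the window, ms.
#' @param drift total linear RR change over the window, ms.
#' @param a_lf,a_hf modulation amplitudes, ms.
#' @param f_lf,f_hf modulation frequencies, Hz (defaults 0.10 and 0.25, inside
#'   the LF and HF bands).
#' @param noise_sd per-beat Gaussian noise, ms.
#' @param vas_mu,vas_sd mean and sd of the period's VAS score (0-100 scale).
#' @param vas_missing_prob probability that a VAS score is missing.
#' @return A list of class `period_spec`.
#' @export
period_spec <- function(label, base_rr, drift = 0, a_lf = 30, a_hf = 30,
                        f_lf = 0.10, f_hf = 0.25, noise_sd = 10,
                        vas_mu = 10, vas_sd = 10, vas_missing_prob = 0.05) {
  if (base_rr <= 0) stop("period_spec: base_rr must be positive")
  if (f_lf < 0.04 || f_lf >= 0.15) stop("period_spec: f_lf outside the LF band")
  if (f_hf < 0.15 || f_hf >= 0.40) stop("period_spec: f_hf outside the HF band")
  if (a_lf < 0 || a_hf < 0 || noise_sd < 0)
    stop("period_spec: amplitudes and noise_sd must be >= 0")
  structure(list(label = label, base_rr = base_rr, drift = drift,
                 a_lf = a_lf, a_hf = a_hf, f_lf = f_lf, f_hf = f_hf,
                 noise_sd = noise_sd, vas_mu = vas_mu, vas_sd = vas_sd,
                 vas_missing_prob = vas_missing_prob),
            class = "period_spec")
}

#' Default period specifications of the simulated stress protocol
#'
#' Nine periods: waiting (T1-T2), stress test (T3: speech preparation,
#' T4: speech delivery, T5: arithmetic), recovery (T6-T9). Baselines follow
#' the typical course of a TSST cohort (rest ~855 ms, stress nadir 616 ms,
#' recovery ~885 ms); stress windows combine a shortened baseline, stronger
#' slow (LF) modulation, weaker fast (HF) modulation, less beat-to-beat noise
#' and a larger within-window drift. VAS scores rise from ~5 at rest to ~59
#' at the arithmetic task and decay through recovery.
#'
#' @return List of nine [period_spec()] objects named T1..T9.
#' @export
default_period_specs <- function() {
  tab <- list(
    #          base  drift a_lf a_hf noise vas_mu vas_sd
    T1 = list( 855,   60,   34,  30,  14,    5,    8),
    T2 = list( 813,  -60,   35,  29,  13,    6,    8),
    T3 = list( 750,  -90,   38,  25,  11,   39,   20),
    T4 = list( 616, -120,   45,  15,   7,   36,   22),
    T5 = list( 672,  100,   42,  16,   9,   59,   25),
    T6 = list( 839,   80,   36,  31,  13,   16,   12),
    T7 = list( 882,  -60,   34,  33,  13,   10,    9),
    T8 = list( 853,   50,   34,  33,  13,    6,    7),
    T9 = list( 885,  -50,   32,  31,  13,    3,    5))
  out <- lapply(names(tab), function(lb) {
    v <- tab[[lb]]
    period_spec(lb, base_rr = v[[1]], drift = v[[2]], a_lf = v[[3]],
                a_hf = v[[4]], noise_sd = v[[5]], vas_mu = v[[6]],
                vas_sd = v[[7]])
  })
  names(out) <- names(tab)
  out
}

# instantaneous RR (ms) at time t (s) under a period spec with given phases
instantaneous_rr <- function(spec, t_rel, dur_s, phi1, phi2) {
  spec$base_rr + spec$drift * (t_rel / dur_s - 0.5) +
    spec$a_lf * sin(2 * pi * spec$f_lf * t_rel + phi1) +
    spec$a_hf * sin(2 * pi * spec$f_hf * t_rel + phi2)
}

#' Generate the beat series of a single analysis window
#'
#' Beats are stepped through the instantaneous tachogram:
#' `t[n+1] = t[n] + r(t[n])/1000` seconds, starting at 0, until the window
#' duration is covered (the final beat may overshoot so the last interval's
#' onset still falls inside the window). Modulation phases are drawn
#' uniformly. With `ectopic_prob > 0` individual beats are displaced towards
#' their predecessor and labeled ventricular, exercising the ectopic
#' interpolation stage.
#'
#' @param spec a [period_spec()].
#' @param seed optional integer seed (caller's RNG state is restored).
#' @param duration_s window length in seconds.
#' @param ectopic_prob per-beat probability of an injected ventricular beat.
#' @return A [beat_series()].
#' @export
generate_window <- function(spec, seed = NULL, duration_s = 300,
                            ectopic_prob = 0) {
  stopifnot(inherits(spec, "period_spec"))
  with_local_seed(seed, {
    phi1 <- runif(1, 0, 2 * pi)
    phi2 <- runif(1, 0, 2 * pi)
    times <- numeric(ceiling(1000 * duration_s / 200) + 8L)
    t <- 0; j <- 1L
    while (t < duration_s) {
      r <- instantaneous_rr(spec, t, duration_s, phi1, phi2) +
        (if (spec$noise_sd > 0) rnorm(1, 0, spec$noise_sd) else 0)
      if (r < 100)
        stop("generate_window: instantaneous RR became non-positive or fell below 100 ms; check spec")
      t <- t + r / 1000
      j <- j + 1L
      if (j > length(times)) times <- c(times, numeric(length(times)))
      times[j] <- t
    }
    times <- times[1:j] * 1000
    labels <- rep("N", j)
    if (ectopic_prob > 0 && j > 3L) {
      cand <- which(runif(j - 2L) < ectopic_prob) + 1L  # never first or last
      for (b in cand) {
        times[b] <- times[b] - 0.4 * (times[b] - times[b - 1L])
        labels[b] <- "V"
      }
    }
    beat_series(times, labels)
  })
}

# One continuous beat-stepped recording across all periods: the instantaneous
# tachogram switches period parameters as time crosses each 5-min boundary, so
# no artifact interval is created at window seams. Consumes the current RNG
# stream (phases, per-beat noise, ectopic draws).
generate_recording <- function(periods, offset = 0, ectopic_prob = 0,
                               dur_s = 300) {
  n_per <- length(periods)
  phis <- matrix(runif(2 * n_per, 0, 2 * pi), ncol = 2)
  total <- n_per * dur_s
  times <- numeric(ceiling(total * 1000 / 200) + 8L)
  t <- 0; j <- 1L
  while (t < total) {
    w <- min(floor(t / dur_s) + 1, n_per)
    sp <- periods[[w]]
    t_rel <- t - (w - 1) * dur_s
    r <- offset + instantaneous_rr(sp, t_rel, dur_s, phis[w, 1], phis[w, 2]) +
      (if (sp$noise_sd > 0) rnorm(1, 0, sp$noise_sd) else 0)
    if (r < 100)
      stop("generate_recording: instantaneous RR became non-positive or fell below 100 ms; check spec")
    t <- t + r / 1000
    j <- j + 1L
    times[j] <- t
  }
  times <- times[1:j] * 1000
  labels <- rep("N", j)
  if (ectopic_prob > 0 && j > 3L) {
    cand <- which(runif(j - 2L) < ectopic_prob) + 1L
    for (b in cand) {
      times[b] <- times[b] - 0.4 * (times[b] - times[b - 1L])
      labels[b] <- "V"
    }
  }
  list(times = times, labels = labels)
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects (default 24).
#' @param n_female number of female subjects (default 12); the remainder are
#'   male. Gender has no built-in effect on the generated physiology.
#' @param periods list of nine [period_spec()]s named T1..T9.
#' @param between_subject_sd sd of the per-subject baseline RR offset, ms.
#' @param ectopic_prob per-beat probability of an injected ventricular beat.
#' @param seed master seed; all randomness flows from it through per-subject
#'   substreams.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24, n_female = 12,
                        periods = default_period_specs(),
                        between_subject_sd = 60, ectopic_prob = 0.002,
                        seed = 1) {
  if (n_subjects < 2L) stop("cohort_spec: need >= 2 subjects")
  if (n_female < 0L || n_female > n_subjects)
    stop("cohort_spec: n_female must be between 0 and n_subjects")
  if (length(periods) != 9L || !identical(names(periods), paste0("T", 1:9)))
    stop("cohort_spec: periods must be nine specs named T1..T9")
  structure(list(n_subjects = n_subjects, n_female = n_female,
                 periods = periods, between_subject_sd = between_subject_sd,
                 ectopic_prob = ectopic_prob, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic TSST cohort
#'
#' Per subject: a baseline offset `~ N(0, between_subject_sd^2)` is added to
#' every period's `base_rr`, the nine windows are generated back to back
#' (markers at the end of each window, i.e. at 300 s, 600 s, ..., 2700 s) as
#' one continuous beat series, and a VAS score is drawn per period from
#' `N(vas_mu, vas_sd)` clipped to [0, 100] and dropped with
#' `vas_missing_prob`. A fixed master seed makes the whole cohort, including
#' every emitted file, exactly reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `subjects` (list
#'   of `id`, `gender`, `beats`, `markers`), `vas` (data.frame
#'   `subject,period,score`), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  dur_s <- 300
  labels9 <- paste0("T", 1:9)
  markers <- data.frame(label = labels9, time_ms = 300000 * (1:9))
  with_local_seed(spec$seed, {
    subj_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
    gender <- rep(c("f", "m"), c(spec$n_female, spec$n_subjects - spec$n_female))
    subjects <- vector("list", spec$n_subjects)
    vas_rows <- list()
    for (s in seq_len(spec$n_subjects)) {
      id <- sprintf("S%02d", s)
      set.seed(subj_seeds[s])
      offset <- rnorm(1, 0, spec$between_subject_sd)
      beats <- generate_recording(spec$periods, offset, spec$ectopic_prob,
                                  dur_s)
      all_times <- beats$times
      all_labels <- beats$labels
      score <- vapply(spec$periods, function(p)
        min(100, max(0, round(rnorm(1, p$vas_mu, p$vas_sd)))), numeric(1))
      miss <- vapply(spec$periods, function(p)
        runif(1) < p$vas_missing_prob, logical(1))
      score[miss] <- NA_real_
      vas_rows[[s]] <- data.frame(subject = id, period = labels9,
                                  score = score, row.names = NULL)
      subjects[[s]] <- list(id = id, gender = gender[s],
                            beats = beat_series(all_times, all_labels,
                                                subject_id = id),
                            markers = markers)
    }
    structure(list(subjects = subjects, vas = do.call(rbind, vas_rows),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits one beat-annotation CSV and one tachogram per subject, a shared
#' marker CSV, and the VAS table - the same formats [read_beats()],
#' [read_tachogram()], [read_markers()] and [read_vas()] consume, so the
#' generator is a drop-in stand-in for a recording session.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_beats(s$beats, file.path(dir, sprintf("subject_%s_beats.csv", s$id)))
    write_tachogram(beats_to_rr(replace_ectopic(s$beats)),
                    file.path(dir, sprintf("subject_%s_tachogram.txt", s$id)))
  }
  write_markers(cohort$subjects[[1]]$markers, file.path(dir, "markers.csv"))
  write_vas(cohort$vas, file.path(dir, "vas.csv"))
  genders <- data.frame(
    subject = vapply(cohort$subjects, `[[`, character(1), "id"),
    gender = vapply(cohort$subjects, `[[`, character(1), "gender"))
  write.csv(genders, file.path(dir, "gender.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
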