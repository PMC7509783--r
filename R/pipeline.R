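# Orchestration: per-subject window analysis and cohort-level aggregation,
# reproducing the shape of the study's summary tables (per-period median, IQR
# and significant-pairs rows for every HRV and symbolic parameter).

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain; defaults are the study
#' configuration (5-min windows, tau = 35 ms, 4 Hz/2048-point spectra,
#' segmentation with min length 40 at significance 0.95, RWS with 8x50).
#'
#' @param window_ms analysis window length, ms.
#' @param tau threshold of the second symbolic encoding, ms.
#' @param spectral a [spectral_config()].
#' @param min_seg_len,seg_sig segmentation parameters.
#' @param rws_n_sub,rws_sub_len RWS parameters.
#' @param sd_denominator SDNN denominator, `"n-1"` or `"n"`.
#' @param seed integer; per-window RWS seeds are derived from it so a fixed
#'   configuration yields byte-identical outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_ms = 300000, tau = 35,
                            spectral = spectral_config(),
                            min_seg_len = 40, seg_sig = 0.95,
                            rws_n_sub = 8, rws_sub_len = 50,
                            sd_denominator = "n-1", seed = 1L) {
  structure(list(window_ms = window_ms, tau = tau, spectral = spectral,
                 min_seg_len = min_seg_len, seg_sig = seg_sig,
                 rws_n_sub = rws_n_sub, rws_sub_len = rws_sub_len,
                 sd_denominator = sd_denominator, seed = seed),
            class = "pipeline_config")
}

# names of the per-window parameter columns produced by run_subject
window_parameters <- function() {
  c("mean_rr", "sdnn", "rmssd",
    "lf", "hf", "ln_lf", "ln_hf", "lf_hf", "lf_pct", "hf_pct", "total_power",
    "p0v_pct", "p1v_pct", "p2v_pct",
    "p0v_tau_pct", "p1v_tau_pct", "p2v_tau_pct",
    "n_segments", "rws_p_mean", "rws_p_var")
}

#' Analyze all marked windows of one subject
#'
#' Stage order: ectopic correction, RR extraction, then per marked window
#' time-domain, spectral, both symbolic distributions, segmentation and the
#' RWS test. A window the recording does not cover is reported as a row of
#' `NA`s (with a warning) and the run continues.
#'
#' @param beats a [beat_series()].
#' @param markers data.frame with columns `label` (T1..T9) and `time_ms`.
#' @param config a [pipeline_config()].
#' @param subject_id optional identifier (defaults to the one in `beats`).
#' @return data.frame of class `subject_report`, one row per marker, columns
#'   `subject`, `window`, `n_intervals`, the parameters of
#'   `window_parameters()`, `stationary_flag` and `n_corrected`.
#' @export
run_subject <- function(beats, markers, config = pipeline_config(),
                        subject_id = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(subject_id)) subject_id <- beats$subject_id
  if (is.null(subject_id)) subject_id <- "subject"
  if (!all(markers$label %in% paste0("T", 1:9)))
    stop("run_subject: marker labels must be within T1..T9")
  corrected <- replace_ectopic(beats)
  n_corrected <- attr(corrected, "n_replaced")
  rr <- beats_to_rr(corrected)
  rows <- vector("list", nrow(markers))
  for (w in seq_len(nrow(markers))) {
    lab <- markers$label[w]
    vals <- rep(NA_real_, length(window_parameters()))
    names(vals) <- window_parameters()
    n_int <- NA_integer_; flag <- NA
    analyzed <- tryCatch({
      win <- extract_window(rr, analysis_window(markers$time_ms[w], lab,
                                                config$window_ms))
      td <- time_domain(win, config$sd_denominator)
      sp <- spectral_analysis(win, config$spectral)
      sy <- symbolic_analysis(win, config$tau)
      seg <- segment_series(win, config$min_seg_len, config$seg_sig)
      rws <- rws_test(win, config$rws_n_sub, config$rws_sub_len,
                      seed = if (is.null(config$seed)) NULL
                             else (config$seed + 7L * w) %% 2147483646L + 1L)
      list(n_int = length(win$rr),
           vals = c(td$mean_rr, td$sdnn, td$rmssd,
                    sp$lf, sp$hf, sp$ln_lf, sp$ln_hf, sp$lf_hf_ratio,
                    sp$lf_pct, sp$hf_pct, sp$total_power,
                    sy$sign$p0v_pct, sy$sign$p1v_pct, sy$sign$p2v_pct,
                    sy$threshold$p0v_pct, sy$threshold$p1v_pct,
                    sy$threshold$p2v_pct,
                    seg$n_segments, rws$p_mean, rws$p_var),
           flag = seg$stationary && rws$stationary)
    }, error = function(e) {
      warning(sprintf("run_subject: window %s skipped (%s)", lab,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(analyzed)) {
      n_int <- analyzed$n_int
      vals[] <- analyzed$vals
      flag <- analyzed$flag
    }
    rows[[w]] <- data.frame(subject = subject_id, window = lab,
                            n_intervals = n_int, t(vals),
                            stationary_flag = flag,
                            n_corrected = n_corrected, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subject_report", class(out))
  out
}

# stack per-subject reports into one cohort matrix per parameter
build_cohort_matrix <- function(reports, parameter) {
  labs <- paste0("T", 1:9)
  subs <- unique(unlist(lapply(reports, function(r) r$subject[1])))
  m <- matrix(NA_real_, length(subs), length(labs),
              dimnames = list(subs, labs))
  for (r in reports)
    m[r$subject[1], r$window] <- r[[parameter]]
  attr(m, "parameter") <- parameter
  m
}

#' Cohort-level statistics over all subjects
#'
#' Builds a subjects-by-periods matrix per parameter; LF, HF and LF/HF enter
#' the statistics ln-transformed (`ln_lf`, `ln_hf`, `ln_lf_hf`), matching the
#' skew-correcting convention of HRV reporting. Per parameter: median/IQR
#' descriptives, Friedman omnibus (Skillings-Mack for the VAS scores, which
#' may have missing values), Holm-adjusted pairwise post-hocs on significant
#' omnibus results, and per-period Mann-Whitney gender contrasts when a
#' gender vector is supplied.
#'
#' @param reports list of `subject_report`s from [run_subject()].
#' @param vas optional VAS data.frame (`subject`, `period`, `score`).
#' @param gender optional named character vector (`"f"`/`"m"` by subject id).
#' @param config a [pipeline_config()].
#' @param parameters parameter columns to analyze; default all of
#'   `window_parameters()` with LF/HF/LF-HF replaced by their ln forms.
#' @return A list of class `cohort_result`: `descriptives`, `omnibus`,
#'   `posthoc` (list by parameter), `gender_tests`, `matrices`.
#' @export
run_cohort <- function(reports, vas = NULL, gender = NULL,
                       config = pipeline_config(), parameters = NULL) {
  if (length(reports) < 2L) stop("run_cohort: need >= 2 subjects")
  if (is.null(parameters))
    parameters <- c("mean_rr", "sdnn", "rmssd", "ln_lf", "ln_hf", "ln_lf_hf",
                    "lf_pct", "hf_pct",
                    "p0v_pct", "p1v_pct", "p2v_pct",
                    "p0v_tau_pct", "p1v_tau_pct", "p2v_tau_pct",
                    "n_segments")
  # derived ln(LF/HF) column per report
  reports <- lapply(reports, function(r) {
    r$ln_lf_hf <- log(r$lf_hf)
    r
  })
  matrices <- lapply(parameters, function(p) build_cohort_matrix(reports, p))
  names(matrices) <- parameters
  if (!is.null(vas)) {
    labs <- paste0("T", 1:9)
    subs <- unique(vas$subject)
    vm <- matrix(NA_real_, length(subs), length(labs),
                 dimnames = list(subs, labs))
    for (i in seq_len(nrow(vas)))
      vm[vas$subject[i], vas$period[i]] <- vas$score[i]
    matrices$vas <- vm
  }
  drop <- vapply(matrices, function(m) all(is.na(m)), logical(1))
  if (any(drop)) {
    warning("run_cohort: excluding all-missing parameter(s): ",
            paste(names(matrices)[drop], collapse = ", "))
    matrices <- matrices[!drop]
  }
  descriptives <- do.call(rbind, lapply(names(matrices), function(p) {
    d <- describe_periods(matrices[[p]])
    cbind(parameter = p, d)
  }))
  omnibus <- lapply(names(matrices), function(p) {
    m <- matrices[[p]]
    if (p == "vas" || anyNA(m)) skillings_mack(m) else friedman_cohort(m)
  })
  names(omnibus) <- names(matrices)
  posthoc <- lapply(names(matrices), function(p)
    posthoc_periods(matrices[[p]], omnibus[[p]]))
  names(posthoc) <- names(matrices)
  gender_tests <- NULL
  if (!is.null(gender)) {
    gender_tests <- do.call(rbind, lapply(names(matrices), function(p) {
      m <- matrices[[p]]
      do.call(rbind, lapply(colnames(m), function(lab) {
        a <- m[gender[rownames(m)] == "f", lab]
        b <- m[gender[rownames(m)] == "m", lab]
        p_val <- if (sum(!is.na(a)) && sum(!is.na(b)))
          mann_whitney(a, b)$p.value else NA_real_
        data.frame(parameter = p, period = lab, p = p_val)
      }))
    }))
  }
  structure(list(descriptives = descriptives, omnibus = omnibus,
                 posthoc = posthoc, gender_tests = gender_tests,
                 matrices = matrices),
            class = "cohort_result")
}

#' Write the cohort result as summary-table CSVs
#'
#' One `cohort_<parameter>_table.csv` per parameter in the shape of the
#' study's summary tables - a median row, an IQR row (`q25-q75`) and a row
#' listing the periods each period differs from significantly - plus a
#' `stationarity_summary.csv` and an `omnibus_tests.csv`.
#'
#' @param result a `cohort_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(result$matrices)) {
    d <- result$descriptives[result$descriptives$parameter == p, ]
    ph <- result$posthoc[[p]]
    sig_row <- vapply(d$period, function(lab) {
      others <- c(ph$period_b[ph$significant & ph$period_a == lab],
                  ph$period_a[ph$significant & ph$period_b == lab])
      paste(others[order(match(others, paste0("T", 1:9)))], collapse = " ")
    }, character(1))
    tab <- rbind(median = sprintf("%.4g", d$median),
                 iqr = sprintf("%.4g-%.4g", d$q25, d$q75),
                 significant_vs = sig_row)
    colnames(tab) <- d$period
    write.csv(tab, file.path(dir, sprintf("cohort_%s_table.csv", p)),
              quote = TRUE)
  }
  om <- do.call(rbind, lapply(names(result$omnibus), function(p) {
    o <- result$omnibus[[p]]
    data.frame(parameter = p, method = o$method, statistic = o$statistic,
               df = o$df, p = o$p.value, n = o$n)
  }))
  write.csv(om, file.path(dir, "omnibus_tests.csv"), row.names = FALSE)
  if ("n_segments" %in% names(result$matrices)) {
    seg <- describe_periods(result$matrices$n_segments)
    write.csv(seg, file.path(dir, "stationarity_summary.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Plot an RR window with its stationary-segment medians
#'
#' Diagnostic plot: the RR series with horizontal medians of every segment
#' found by [segment_series()] overlaid - one segment means a stationary
#' window.
#'
#' @param rr an [rr_series()] (or numeric vector).
#' @param seg optional `segmentation_result`; computed if missing.
#' @param ... passed to `plot()`.
#' @export
plot_segments <- function(rr, seg = NULL, ...) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (is.null(seg)) seg <- segment_series(x)
  plot(x, type = "l", col = "grey40", xlab = "interval index",
       ylab = "RR (ms)", ...)
  bounds <- c(1L, seg$change_points, length(x) + 1L)
  for (j in seq_len(seg$n_segments))
    segments(bounds[j], seg$segment_medians[j], bounds[j + 1L] - 1L,
             seg$segment_medians[j], col = "red", lwd = 2)
  invisible(seg)
}
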