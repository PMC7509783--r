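#' Annotated beat series
#'
#' Container for R-peak times with per-beat annotations, the raw substrate of
#' every downstream HRV computation. Times are milliseconds from recording
#' start and must be strictly increasing; labels use the conventional
#' single-letter codes `"N"` (normal), `"V"` (ventricular), `"S"`
#' (supraventricular) and `"A"` (artifact).
#'
#' @param times numeric vector, beat times in ms, strictly increasing, all >= 0.
#' @param labels character vector of per-beat labels, recycled if length 1.
#' @param subject_id optional subject identifier.
#' @return An object of class `beat_series`.
#' @examples
#' beat_series(c(0, 800, 1600, 2410))
#' @export
beat_series <- function(times, labels = "N", subject_id = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("beat_series: no beats supplied")
  if (anyNA(times)) stop("beat_series: NA beat times")
  if (any(times < 0)) stop("beat_series: beat times must be >= 0")
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L)
    stop(sprintf("beat_series: times not strictly increasing at index %d", bad[1] + 1L))
  labels <- as.character(labels)
  if (length(labels) == 1L) labels <- rep(labels, length(times))
  if (length(labels) != length(times))
    stop("beat_series: labels must match times in length")
  unknown <- setdiff(unique(labels), c("N", "V", "S", "A"))
  if (length(unknown) > 0L)
    stop("beat_series: unknown beat labels: ", paste(unknown, collapse = ", "))
  structure(list(times = times, labels = labels, subject_id = subject_id),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s", length(x$times),
              (x$times[length(x$times)] - x$times[1]) / 1000))
  nn <- sum(x$labels != "N")
  if (nn > 0) cat(sprintf(", %d non-normal", nn))
  if (!is.null(x$subject_id)) cat(", subject ", x$subject_id)
  cat("\n")
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times)

#' RR interval series (tachogram)
#'
#' The sequence of interbeat intervals \eqn{RR_i} (ms) together with the onset
#' time of each interval. All analyses in the package consume this object.
#' Values outside the physiologic range 200-3000 ms trigger a warning but are
#' kept: the guard flags suspect recordings without censoring them.
#'
#' @param rr numeric vector of RR intervals in ms, all > 0.
#' @param start_times optional onset time (ms) of each interval; defaults to
#'   the cumulative sum starting at 0.
#' @param window_label optional analysis-period tag (`"T1"`..`"T9"`).
#' @param subject_id optional subject identifier.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr, start_times = NULL, window_label = NULL,
                      subject_id = NULL) {
  rr <- as.numeric(rr)
  if (length(rr) < 1L) stop("rr_series: empty series")
  if (anyNA(rr)) stop("rr_series: NA intervals")
  if (any(rr <= 0)) stop("rr_series: RR intervals must be positive")
  if (any(rr < 200 | rr > 3000))
    warning("rr_series: intervals outside the physiologic 200-3000 ms range")
  if (is.null(start_times)) start_times <- cumsum(c(0, rr[-length(rr)]))
  start_times <- as.numeric(start_times)
  if (length(start_times) != length(rr))
    stop("rr_series: start_times must match rr in length")
  structure(list(rr = rr, start_times = start_times,
                 window_label = window_label, subject_id = subject_id),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> N=%d, mean RR %.1f ms", length(x$rr), mean(x$rr)))
  if (!is.null(x$window_label)) cat(", window ", x$window_label)
  cat("\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

#' Derive the RR interval series from beat times
#'
#' `rr[i] = times[i+1] - times[i]`; each interval carries the onset time of its
#' first beat, so the cumulative sum of intervals added to the first beat time
#' reconstructs the beat series exactly.
#'
#' @param beats a [beat_series()].
#' @return An [rr_series()] of length `length(beats) - 1`.
#' @examples
#' beats_to_rr(beat_series(c(0, 800, 1600, 2410)))$rr # 800 800 810
#' @export
beats_to_rr <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times) < 2L)
    stop("beats_to_rr: need at least 2 beats to form an interval")
  rr_series(diff(beats$times),
            start_times = beats$times[-length(beats$times)],
            subject_id = beats$subject_id)
}

#' Replace ectopic beats by interpolated times
#'
#' Beats labeled ventricular, supraventricular or artifact are replaced by
#' linearly interpolated times between the flanking normal beats: a run of
#' `m` non-normal beats between normal anchors at `t_a`, `t_b` is respaced to
#' `t_a + j*(t_b - t_a)/(m+1)`, `j = 1..m`, and relabeled normal. Leading or
#' trailing non-normal beats have no anchors and are trimmed (with a warning).
#' The total beat count between the first and last normal beat is preserved.
#'
#' @param beats a [beat_series()].
#' @return A `beat_series` of all-normal beats; the number of replaced beats is
#'   attached as attribute `n_replaced` (trimmed beats as `n_trimmed`).
#' @export
replace_ectopic <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  normal <- beats$labels == "N"
  if (!any(normal)) stop("replace_ectopic: no normal beats to anchor on")
  n <- length(beats$times)
  first <- which(normal)[1]
  last <- which(normal)[sum(normal)]
  n_trim <- (first - 1L) + (n - last)
  if (n_trim > 0L)
    warning(sprintf("replace_ectopic: trimmed %d edge beat(s) without normal anchors", n_trim))
  times <- beats$times[first:last]
  labels <- beats$labels[first:last]
  non_normal <- which(labels != "N")
  frac <- length(non_normal) / length(labels)
  if (frac > 0.05)
    warning(sprintf("replace_ectopic: %.1f%% non-normal beats (expected < 1%%)", 100 * frac))
  if (length(non_normal) > 0L) {
    # contiguous runs of non-normal beats, each flanked by normal anchors
    runs <- split(non_normal, cumsum(c(1L, diff(non_normal) != 1L)))
    for (run in runs) {
      a <- run[1] - 1L
      b <- run[length(run)] + 1L
      m <- length(run)
      times[run] <- times[a] + seq_len(m) * (times[b] - times[a]) / (m + 1)
    }
    labels[non_normal] <- "N"
  }
  out <- beat_series(times, labels, subject_id = beats$subject_id)
  attr(out, "n_replaced") <- length(non_normal)
  attr(out, "n_trimmed") <- n_trim
  out
}

#' Define a 5-minute analysis window ending at a protocol marker
#'
#' Protocol markers are set at the end of each analysis period; the window
#' covers the preceding `duration_ms` (default 5 min), as the half-open span
#' `[marker_time - duration_ms, marker_time)`.
#'
#' @param marker_time marker time in ms.
#' @param label window tag, one of `"T1"`..`"T9"`.
#' @param duration_ms window length in ms (default 300000).
#' @export
analysis_window <- function(marker_time, label, duration_ms = 300000) {
  if (!label %in% paste0("T", 1:9))
    stop("analysis_window: label must be one of T1..T9")
  if (marker_time < duration_ms)
    stop("analysis_window: window would start before the recording")
  structure(list(marker_time = as.numeric(marker_time), label = label,
                 duration_ms = duration_ms),
            class = "analysis_window")
}

#' Extract the intervals of one analysis window
#'
#' Membership is by interval onset in the half-open span
#' `[marker - duration, marker)`; an interval beginning exactly at the marker
#' belongs to the next window, so adjacent windows never share an interval.
#'
#' @param rr an [rr_series()] covering the window.
#' @param window an [analysis_window()].
#' @return An `rr_series` tagged with the window label.
#' @export
extract_window <- function(rr, window) {
  stopifnot(inherits(rr, "rr_series"), inherits(window, "analysis_window"))
  lo <- window$marker_time - window$duration_ms
  if (lo < rr$start_times[1] - 1e-6)
    stop(sprintf("extract_window: window %s starts before the recording", window$label))
  keep <- rr$start_times >= lo & rr$start_times < window$marker_time
  if (!any(keep))
    stop(sprintf("extract_window: no intervals fall in window %s", window$label))
  rr_series(rr$rr[keep], start_times = rr$start_times[keep],
            window_label = window$label, subject_id = rr$subject_id)
}

#' Successive RR differences
#'
#' \eqn{\Delta RR_i = RR_{i+1} - RR_i}: the difference series underlying both
#' symbolic encodings and RMSSD. Length is one less than the parent series and
#' `rr[1] + cumsum(drr)` reconstructs it exactly.
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @return An object of class `diff_series` with field `drr` (ms).
#' @export
rr_diff <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$rr) < 2L) stop("rr_diff: need at least 2 intervals")
  structure(list(drr = diff(rr$rr), window_label = rr$window_label),
            class = "diff_series")
}

#' @export
length.diff_series <- function(x) length(x$drr)
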