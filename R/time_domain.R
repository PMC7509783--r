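#' Time-domain HRV parameters for one analysis window
#'
#' The classical short-term triple: the mean RR interval, SDNN (standard
#' deviation of the intervals) and RMSSD (root mean square of successive
#' differences). RMSSD reflects beat-to-beat, vagally mediated variability;
#' SDNN total variability over the window.
#'
#' SDNN uses the sample (N-1) denominator by default, the convention of most
#' HRV software; set `sd_denominator = "n"` for the population form.
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return A list of class `time_domain_result` with fields `mean_rr`, `sdnn`,
#'   `rmssd` (all ms) and `n_intervals`.
#' @examples
#' time_domain(rr_series(c(800, 820)))  # mean 810, sdnn 14.14, rmssd 20
#' @export
time_domain <- function(rr, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(rr, "rr_series"))
  sd_denominator <- match.arg(sd_denominator)
  x <- rr$rr
  n <- length(x)
  if (n < 2L) stop("time_domain: need at least 2 intervals")
  sdnn <- sd(x)
  if (sd_denominator == "n") sdnn <- sdnn * sqrt((n - 1) / n)
  structure(list(mean_rr = mean(x),
                 sdnn = sdnn,
                 rmssd = sqrt(mean(diff(x)^2)),
                 n_intervals = n),
            class = "time_domain_result")
}
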