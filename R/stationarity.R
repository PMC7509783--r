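# Two nonstationarity diagnostics for 5-min RR windows: recursive heuristic
# segmentation (split at the maximal pooled-variance t-statistic, accept by
# the Bernaola-Galvan significance approximation) and the restricted weak
# stationarity (RWS) test on randomly drawn subsequences.

# cap for the t-statistic when the pooled variance vanishes but means differ
T_SENTINEL <- 1e6

#' Pooled-variance split statistic
#'
#' The two-sample t-statistic contrasting the mean left and right of a split:
#' `t(i) = |mean(left) - mean(right)| / s_D` with
#' `s_D = s_pooled * sqrt(1/n_left + 1/n_right)`. A degenerate split (zero
#' pooled variance) returns 0 when the means agree and a capped sentinel,
#' treated as maximally significant, when they differ.
#'
#' @param x numeric series.
#' @param i split index: the left segment is `x[1:i]`, 2 <= i <= length(x)-2.
#' @return The t-value.
#' @examples
#' split_statistic(c(1, 2, 3, 4, 5, 6), 3)  # 3.674
#' @export
split_statistic <- function(x, i) {
  n <- length(x)
  if (i < 2L || i > n - 2L) stop("split_statistic: both sides need >= 2 points")
  l <- x[1:i]; r <- x[(i + 1):n]
  sp2 <- (sum((l - mean(l))^2) + sum((r - mean(r))^2)) / (n - 2)
  s_d <- sqrt(sp2 * (1 / i + 1 / (n - i)))
  dm <- abs(mean(l) - mean(r))
  if (s_d == 0) return(if (dm < .Machine$double.eps^0.5) 0 else T_SENTINEL)
  min(dm / s_d, T_SENTINEL)
}

# t-values at every admissible split (both sides >= min_len), vectorized.
split_t_profile <- function(x, min_len) {
  n <- length(x)
  cs <- cumsum(x); css <- cumsum(x * x)
  i <- min_len:(n - min_len)
  ml <- cs[i] / i
  mr <- (cs[n] - cs[i]) / (n - i)
  ssl <- pmax(css[i] - cs[i]^2 / i, 0)
  ssr <- pmax((css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i), 0)
  s_d <- sqrt((ssl + ssr) / (n - 2) * (1 / i + 1 / (n - i)))
  dm <- abs(ml - mr)
  tv <- ifelse(s_d == 0,
               ifelse(dm < .Machine$double.eps^0.5, 0, T_SENTINEL),
               pmin(dm / s_d, T_SENTINEL))
  list(i = i, tv = tv)
}

# Bernaola-Galvan approximation to the significance of the maximal t:
# P(t_max) = {1 - I_[nu/(nu+t^2)](delta*nu, delta)}^eta, nu = n - 2,
# eta = 4.19 ln(n) - 11.54, delta = 0.40.
bg_significance <- function(t_max, n, delta = 0.40, eta = NULL) {
  nu <- n - 2
  if (is.null(eta)) eta <- 4.19 * log(n) - 11.54
  (1 - pbeta(nu / (nu + t_max^2), delta * nu, delta))^eta
}

#' Heuristic segmentation of an RR series into stationary segments
#'
#' Recursive procedure: find the split maximizing the pooled-variance
#' t-statistic among all splits leaving both sides at least `min_len` points;
#' accept it when its Bernaola-Galvan significance reaches `sig`; recurse into
#' both halves. The default `min_len = 40` intervals keeps LF-band
#' fluctuations from fragmenting a window. A window is judged stationary iff
#' it is not segmented at all. The algorithm is deterministic.
#'
#' @param x numeric vector of RR intervals (ms), or an [rr_series()] /
#'   `diff_series`.
#' @param min_len minimum segment length in intervals.
#' @param sig significance threshold for accepting a split.
#' @param delta,eta constants of the significance approximation; `eta = NULL`
#'   uses the published `4.19 ln(n) - 11.54`.
#' @return A list of class `segmentation_result`: `change_points` (1-based
#'   index of the first sample of each new segment), `n_segments`,
#'   `segment_medians`, `stationary`, plus the parameters used.
#' @export
segment_series <- function(x, min_len = 40, sig = 0.95, delta = 0.40,
                           eta = NULL) {
  if (inherits(x, "rr_series")) x <- x$rr
  if (inherits(x, "diff_series")) x <- x$drr
  x <- as.numeric(x)
  min_len <- as.integer(min_len)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * min_len) return(integer(0))
    prof <- split_t_profile(x[lo:hi], min_len)
    k <- which.max(prof$tv)
    p <- bg_significance(prof$tv[k], n, delta, eta)
    if (!is.finite(p) || p < sig) return(integer(0))
    cp_local <- prof$i[k]               # size of the left segment
    cp <- lo + cp_local                 # global index of first right sample
    c(recurse(lo, cp - 1L), cp, recurse(cp, hi))
  }
  cps <- recurse(1L, length(x))
  bounds <- c(1L, cps, length(x) + 1L)
  medians <- vapply(seq_len(length(bounds) - 1L), function(j)
    median(x[bounds[j]:(bounds[j + 1L] - 1L)]), numeric(1))
  structure(list(change_points = cps, n_segments = length(cps) + 1L,
                 segment_medians = medians, stationary = length(cps) == 0L,
                 min_len = min_len, sig = sig),
            class = "segmentation_result")
}

#' Restricted weak stationarity (RWS) test
#'
#' Draws `n_sub` random subsequences of `sub_len` intervals (start indices
#' without replacement; overlap permitted, which is unavoidable at typical
#' 5-min window lengths of ~340-480 intervals) and tests whether their means
#' and their variances are compatible across subsequences. The default
#' components are nonparametric: Kruskal-Wallis for location and
#' Brown-Forsythe (Levene on medians) for dispersion;
#' `method = "parametric"` substitutes one-way ANOVA and Bartlett's test.
#' A series is considered weakly stationary when both p-values exceed 0.05.
#'
#' @param x numeric vector, [rr_series()] or `diff_series`.
#' @param n_sub number of subsequences.
#' @param sub_len subsequence length in intervals.
#' @param seed integer seed for the subsequence draw (restores the caller's
#'   RNG state); identical seeds give identical draws and p-values.
#' @param method `"rank"` (default) or `"parametric"`.
#' @return A list of class `rws_result`: `p_mean`, `p_var`, `stationary`,
#'   `starts`, and the parameters used.
#' @export
rws_test <- function(x, n_sub = 8, sub_len = 50, seed = NULL,
                     method = c("rank", "parametric")) {
  method <- match.arg(method)
  if (inherits(x, "rr_series")) x <- x$rr
  if (inherits(x, "diff_series")) x <- x$drr
  x <- as.numeric(x)
  n <- length(x)
  if (n < sub_len)
    stop(sprintf("rws_test: series length %d < subsequence length %d", n, sub_len))
  n_starts <- n - sub_len + 1L
  if (n_starts < n_sub)
    stop("rws_test: too few admissible start indices for distinct subsequences")
  starts <- with_local_seed(seed, sort(sample.int(n_starts, n_sub)))
  vals <- unlist(lapply(starts, function(s) x[s:(s + sub_len - 1L)]))
  g <- factor(rep(seq_len(n_sub), each = sub_len))
  if (diff(range(vals)) < .Machine$double.eps) {
    p_mean <- 1; p_var <- 1
  } else if (method == "rank") {
    p_mean <- suppressWarnings(kruskal.test(vals, g)$p.value)
    p_var <- car::leveneTest(vals ~ g, center = median)[["Pr(>F)"]][1]
  } else {
    p_mean <- oneway.test(vals ~ g, var.equal = TRUE)$p.value
    p_var <- bartlett.test(vals, g)$p.value
  }
  # a location/dispersion test can degenerate if some groups are constant
  if (!is.finite(p_mean)) p_mean <- 1
  if (!is.finite(p_var)) p_var <- 1
  structure(list(p_mean = p_mean, p_var = p_var,
                 stationary = p_mean > 0.05 && p_var > 0.05,
                 n_sub = n_sub, sub_len = sub_len, seed = seed,
                 starts = starts, method = method),
            class = "rws_result")
}
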