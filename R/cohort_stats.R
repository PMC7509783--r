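# Nonparametric group-level statistics across the nine analysis periods:
# median/IQR descriptives, Friedman omnibus, Skillings-Mack for matrices with
# missing cells, Holm-adjusted pairwise post-hocs, Mann-Whitney contrasts.

#' Build a subjects-by-periods cohort matrix
#'
#' @param values numeric matrix, rows = subjects, columns = periods; `NA`
#'   marks a missing observation.
#' @param subject_ids,period_labels optional dimnames.
#' @param parameter_name optional name of the measured parameter.
#' @return The matrix with dimnames and a `parameter` attribute set.
#' @export
cohort_matrix <- function(values, subject_ids = NULL, period_labels = NULL,
                          parameter_name = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("cohort_matrix: need >= 2 periods")
  ok_rows <- rowSums(!is.na(values)) >= 2L
  if (sum(ok_rows) < 2L)
    stop("cohort_matrix: need >= 2 subjects with >= 2 observed periods")
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  if (!is.null(period_labels)) colnames(values) <- period_labels
  attr(values, "parameter") <- parameter_name
  values
}

#' Median and interquartile range per period
#'
#' Percentiles use the linear-interpolation convention (R quantile type 7).
#'
#' @param m cohort matrix (subjects x periods), `NA` allowed.
#' @return data.frame with columns `period`, `n`, `median`, `q25`, `q75`.
#' @export
describe_periods <- function(m) {
  m <- as.matrix(m)
  labs <- colnames(m)
  if (is.null(labs)) labs <- paste0("P", seq_len(ncol(m)))
  out <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j][!is.na(m[, j])]
    if (length(v) == 0L)
      data.frame(period = labs[j], n = 0L, median = NA_real_,
                 q25 = NA_real_, q75 = NA_real_)
    else
      data.frame(period = labs[j], n = length(v), median = median(v),
                 q25 = unname(quantile(v, 0.25)),
                 q75 = unname(quantile(v, 0.75)))
  })
  do.call(rbind, out)
}

#' Friedman test for repeated measures across periods
#'
#' Within-subject midranks; the tie-corrected chi-square statistic
#' \deqn{\chi^2 = (k-1) \sum_j (R_j - n(k+1)/2)^2 / \sum_{ij} (r_{ij} - (k+1)/2)^2}
#' which reduces to the classical `12/(nk(k+1))` form when no ties occur.
#' Subjects with any missing period are dropped (listwise); use
#' [skillings_mack()] to retain them.
#'
#' @param m cohort matrix (subjects x periods).
#' @return A list of class `cohort_test` with `statistic`, `df`, `p.value`,
#'   `n` (complete subjects) and `method`.
#' @export
friedman_cohort <- function(m) {
  m <- as.matrix(m)
  cc <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(cc); k <- ncol(cc)
  if (k < 3L) stop("friedman_cohort: need >= 3 periods")
  if (n < 2L)
    stop("friedman_cohort: < 2 complete subjects; use skillings_mack() for incomplete data")
  r <- t(apply(cc, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum((r - (k + 1) / 2)^2)
  stat <- if (den == 0) 0 else num / den
  structure(list(statistic = stat, df = k - 1L,
                 p.value = pchisq(stat, k - 1L, lower.tail = FALSE),
                 n = n, method = "Friedman rank sum test (tie-corrected)"),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: chi-squared = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$df, x$p.value, x$n))
  invisible(x)
}

# connectivity of the observation pattern: periods are linked when some
# subject observes both; the test is valid only on one connected block.
check_connected <- function(obs) {
  k <- ncol(obs)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(nrow(obs))) {
    j <- which(obs[i, ])
    adj[j, j] <- TRUE
  }
  comp <- rep(0L, k); cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Skillings-Mack test for repeated measures with missing data
#'
#' Friedman-type rank statistic tolerating missing cells: per subject the
#' observed periods are midranked, centered, weighted by
#' `sqrt(12/(s_i + 1))` (`s_i` = number of observed periods) and summed into
#' the adjusted vector `A`; the statistic is `A' Sigma^- A` with a generalized
#' inverse of the covariance implied by the observation pattern, referred to a
#' chi-square with `rank(Sigma)` degrees of freedom. On a complete matrix
#' without ties it coincides exactly with the Friedman statistic.
#'
#' @param m cohort matrix (subjects x periods), `NA` = missing.
#' @return A list of class `cohort_test`.
#' @export
skillings_mack <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  obs <- !is.na(m)
  use <- rowSums(obs) >= 2L          # a single observation carries no contrast
  m <- m[use, , drop = FALSE]
  obs <- obs[use, , drop = FALSE]
  if (nrow(m) < 2L) stop("skillings_mack: need >= 2 informative subjects")
  if (any(colSums(obs) == 0L))
    stop("skillings_mack: period(s) with no observations: ",
         paste(colnames(m)[colSums(obs) == 0L], collapse = ", "))
  comp <- check_connected(obs)
  if (length(unique(comp)) > 1L) {
    labs <- colnames(m); if (is.null(labs)) labs <- paste0("P", seq_len(k))
    blocks <- vapply(split(labs, comp), paste, character(1), collapse = ",")
    stop("skillings_mack: disconnected observation pattern; period blocks: {",
         paste(blocks, collapse = "} {"), "}")
  }
  A <- numeric(k)
  for (i in seq_len(nrow(m))) {
    j <- which(obs[i, ])
    s_i <- length(j)
    r <- rank(m[i, j])
    A[j] <- A[j] + sqrt(12 / (s_i + 1)) * (r - (s_i + 1) / 2)
  }
  # covariance of A under the null: Sigma_jj' = -#{i observing both j,j'},
  # Sigma_jj = sum over subjects observing j of (s_i - 1)
  Sigma <- -crossprod(obs)
  diag(Sigma) <- as.vector(t(obs) %*% (rowSums(obs) - 1))
  stat <- drop(t(A) %*% MASS::ginv(Sigma) %*% A)
  df <- qr(Sigma)$rank
  structure(list(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 n = nrow(m), method = "Skillings-Mack test"),
            class = "cohort_test")
}

#' Post-hoc pairwise period comparisons
#'
#' Gated on a significant omnibus test: when `omnibus$p.value >= alpha` an
#' empty result is returned. Default method: Wilcoxon signed-rank on every
#' period pair (paired, midranks) with Holm step-down adjustment over all
#' pairs. `method = "rank-cd"` instead applies the Siegel-Castellan critical
#' difference of Friedman mean ranks at a Bonferroni-type level.
#'
#' @param m cohort matrix (subjects x periods).
#' @param omnibus a `cohort_test` (from [friedman_cohort()] or
#'   [skillings_mack()]).
#' @param method `"wilcoxon-holm"` (default) or `"rank-cd"`.
#' @param alpha significance level.
#' @return data.frame of class `posthoc_result` with columns `period_a`,
#'   `period_b`, `p_raw`, `p_adj`, `significant`; attribute `note` explains an
#'   empty result.
#' @export
posthoc_periods <- function(m, omnibus, method = c("wilcoxon-holm", "rank-cd"),
                            alpha = 0.05) {
  method <- match.arg(method)
  m <- as.matrix(m)
  labs <- colnames(m); if (is.null(labs)) labs <- paste0("P", seq_len(ncol(m)))
  empty <- data.frame(period_a = character(0), period_b = character(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0))
  if (omnibus$p.value >= alpha) {
    attr(empty, "note") <- "omnibus test not significant; no pairwise testing"
    class(empty) <- c("posthoc_result", class(empty))
    return(empty)
  }
  prs <- combn(ncol(m), 2)
  if (method == "wilcoxon-holm") {
    p_raw <- apply(prs, 2, function(jj) {
      a <- m[, jj[1]]; b <- m[, jj[2]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2L) return(NA_real_)
      if (all(a[ok] == b[ok])) return(1)
      suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
    })
    p_adj <- rep(NA_real_, length(p_raw))
    testable <- !is.na(p_raw)
    p_adj[testable] <- p.adjust(p_raw[testable], method = "holm")
    out <- data.frame(period_a = labs[prs[1, ]], period_b = labs[prs[2, ]],
                      p_raw = p_raw, p_adj = p_adj,
                      significant = !is.na(p_adj) & p_adj < alpha)
  } else {
    cc <- m[complete.cases(m), , drop = FALSE]
    n <- nrow(cc); k <- ncol(cc)
    rbar <- colMeans(t(apply(cc, 1, rank)))
    crit <- qnorm(1 - alpha / (k * (k - 1))) * sqrt(k * (k + 1) / (6 * n))
    dif <- abs(rbar[prs[1, ]] - rbar[prs[2, ]])
    out <- data.frame(period_a = labs[prs[1, ]], period_b = labs[prs[2, ]],
                      p_raw = NA_real_, p_adj = NA_real_,
                      significant = dif >= crit)
  }
  class(out) <- c("posthoc_result", class(out))
  out
}

#' Mann-Whitney U test between two independent groups
#'
#' Thin wrapper over [stats::wilcox.test()] (two-sided; exact for small
#' tie-free samples, midrank normal approximation otherwise), used for the
#' gender contrasts.
#'
#' @param a,b numeric vectors, each non-empty (NAs dropped).
#' @return A list of class `cohort_test` with the U statistic for `a`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) stop("mann_whitney: empty group")
  ht <- suppressWarnings(wilcox.test(a, b))
  structure(list(statistic = unname(ht$statistic), df = NA_integer_,
                 p.value = ht$p.value, n = length(a) + length(b),
                 method = "Mann-Whitney U test"),
            class = "cohort_test")
}
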