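#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The two-sided p-value is exact (full
#' enumeration of all C(n, nA) group assignments) when both groups have at
#' most `exactMax` observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exactMax largest per-group size for the exact method (default 8;
#'   enumeration cost is at most C(16,8) = 12870 arrangements).
#' @return list with `u` (U statistic of group a), `p` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`), `nA`, `nB`.
#' @export
mannWhitneyU <- function(a, b, exactMax = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  nA <- length(a); nB <- length(b)
  if (nA < 1 || nB < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks for ties
  u <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && nA <= exactMax && nB <= exactMax) {
    combos <- utils::combn(nA + nB, nA)
    uAll <- colSums(matrix(rk[combos], nrow = nA)) - nA * (nA + 1) / 2
    uLo <- min(u, nA * nB - u)
    p <- min(1, (sum(uAll <= uLo) + sum(uAll >= nA * nB - uLo)) / ncol(combos))
    list(u = u, p = p, method = "exact", nA = nA, nB = nB)
  } else {
    n <- nA + nB
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- nA * nB / 12 * ((n + 1) - tieCorr)
    mu <- nA * nB / 2
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(u = u, p = p, method = "normal_approx", nA = nA, nB = nB)
  }
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper over [stats::t.test()]; when both groups have zero variance
#' and equal means the p-value is defined as 1.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `t`, `dof`, `p` (two-sided).
#' @export
welchTTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, dof = length(a) + length(b) - 2, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                dof = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Compare a spike metric between two groups of cells
#'
#' Mann-Whitney U test on a per-cell summary metric, over the responding
#' cells (cells without spikes have no defined spike means).
#'
#' @param summariesA,summariesB per-cell summary tables from
#'   [summarizeCell()] rows.
#' @param metric column to compare, e.g. `"mean_amplitude_nM"`.
#' @return a [mannWhitneyU()] result with the metric name attached.
#' @export
compareGroups <- function(summariesA, summariesB,
                          metric = "mean_amplitude_nM") {
  va <- summariesA[[metric]]
  vb <- summariesB[[metric]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (!length(va) || !length(vb))
    stop("need at least one non-missing value per group")
  res <- mannWhitneyU(va, vb)
  res$metric <- metric
  res
}
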