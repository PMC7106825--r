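# Statistical test battery and a tidy result wrapper. The module's own
# logic is block pairing and table assembly; the tests themselves are the
# standard stats implementations.

.testResult <- function(name, statistic, p, inputs = "") {
  data.frame(test = name, statistic = unname(statistic),
             p_value = unname(p), inputs = inputs, alpha = 0.05,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1). A
#' zero row or column marginal is an error.
#'
#' @param table r x c matrix of nonnegative counts
#' @return one-row data.frame: test, statistic, p_value, inputs, alpha
#' @export
chi2Contingency <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("chi-squared test requires positive row and column marginals")
  ht <- stats::chisq.test(table, correct = FALSE)
  .testResult("chi-squared", ht$statistic, ht$p.value,
              sprintf("%dx%d table, df=%d", nrow(table), ncol(table),
                      ht$parameter))
}

#' Wilcoxon rank-sum test
#' @param x,y the two groups
#' @return one-row data.frame as in \code{chi2Contingency}
#' @export
wilcoxonRankSum <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  .testResult("Wilcoxon rank-sum", ht$statistic, ht$p.value,
              sprintf("n=%d vs %d", length(x), length(y)))
}

#' Kruskal-Wallis test over groups
#' @param values numeric vector
#' @param groups grouping factor
#' @return one-row data.frame
#' @export
kruskalWallisTest <- function(values, groups) {
  ht <- stats::kruskal.test(values, factor(groups))
  .testResult("Kruskal-Wallis", ht$statistic, ht$p.value,
              sprintf("%d groups", nlevels(factor(groups))))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics on mean ranks with the tie-corrected variance,
#' after a Kruskal-Wallis test; two-sided p-values Bonferroni-adjusted
#' over the number of pairs.
#'
#' @param values numeric vector
#' @param groups grouping factor
#' @return data.frame with one row per pair: comparison, z, p_value,
#'   p_adjusted
#' @export
dunnTest <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanR <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  nPairs <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(nPairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[a] + 1 / n[b]))
    z <- (meanR[a] - meanR[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(a, "-", b), z = unname(z),
               p_value = unname(p),
               p_adjusted = unname(pmin(1, p * nPairs)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test between two smoothed shore profiles
#'
#' Profiles are block-averaged on the identical grid (default 20-position
#' blocks within +/-2000 bp of the border) and compared by a paired t-test
#' over matched blocks; blocks missing on either side are dropped
#' pairwise. Fewer than 3 complete pairs is an error. A zero-variance
#' difference with nonzero mean yields an infinite statistic and p = 0.
#'
#' @param profileA,profileB data.frames from \code{distanceProfile} (raw,
#'   per-position) for the two CGI classes
#' @param window block width in positions (default 20)
#' @param span maximum |distance| considered (default 2000)
#' @param value profile column to compare (default "rate")
#' @return one-row data.frame as in \code{chi2Contingency}
#' @export
pairedTShores <- function(profileA, profileB, window = 20L, span = 2000L,
                          value = "rate") {
  a <- profileA[abs(profileA$distance) <= span, , drop = FALSE]
  b <- profileB[abs(profileB$distance) <= span, , drop = FALSE]
  sa <- smoothProfile(a, window, value)
  sb <- smoothProfile(b, window, value)
  m <- merge(sa[, c("distance", value)], sb[, c("distance", value)],
             by = "distance", suffixes = c(".a", ".b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    .stopf("paired t-test requires >= 3 complete block pairs, got %d",
           nrow(m))
  d <- m[[paste0(value, ".a")]] - m[[paste0(value, ".b")]]
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    return(.testResult("paired t", stat, p,
                       sprintf("%d block pairs (zero-variance difference)",
                               nrow(m))))
  }
  ht <- stats::t.test(m[[paste0(value, ".a")]], m[[paste0(value, ".b")]],
                      paired = TRUE)
  .testResult("paired t", ht$statistic, ht$p.value,
              sprintf("%d block pairs", nrow(m)))
}
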