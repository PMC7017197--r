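#' Two-group differential expression by the conditional binomial exact test
#'
#' Counts are pooled within each group (a = sum over group A, b = sum over
#' group B) and, conditional on the feature total, `a` is tested against
#' `Binomial(a + b, N_A / (N_A + N_B))` where `N_A`, `N_B` are the summed
#' library sizes. The two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (the minimum-likelihood
#' rule, as in [stats::binom.test()]). Fold changes are library-size
#' matched with a 0.5 pseudocount:
#' `log2fc = log2((b + 0.5)/N_B) - log2((a + 0.5)/N_A)`.
#'
#' This test conditions away between-replicate variability: it is exact
#' under Poisson sampling but anti-conservative when counts carry
#' biological overdispersion (see the methods vignette for the measured
#' extent). Benjamini-Hochberg FDR is computed across all tested features.
#'
#' @param counts Integer matrix, features x samples.
#' @param groups Factor (or vector) of two levels, length `ncol(counts)`;
#'   the first level is the reference group A.
#' @param libSizes Per-sample library sizes; defaults to column sums.
#' @return data.frame with `feature_id`, `log2fc`, `p_value`, `fdr`.
#' @export
testTwoGroup <- function(counts, groups, libSizes = colSums(counts)) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 1)) stop("each group needs >= 1 sample")
  if (any(libSizes <= 0)) stop("library sizes must be > 0")
  gA <- groups == levels(groups)[1]
  a <- rowSums(counts[, gA, drop = FALSE])
  b <- rowSums(counts[, !gA, drop = FALSE])
  NA_ <- sum(libSizes[gA]); NB_ <- sum(libSizes[!gA])
  pr <- NA_ / (NA_ + NB_)
  p <- vapply(seq_along(a), function(i) {
    n <- a[i] + b[i]
    if (n == 0) return(1)
    d <- stats::dbinom(0:n, n, pr)
    min(1, sum(d[d <= d[a[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
  lfc <- log2((b + 0.5) / NB_) - log2((a + 0.5) / NA_)
  lfc[a + b == 0] <- 0
  data.frame(feature_id = rownames(counts), log2fc = lfc, p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold profiles used for the three RNA classes
#'
#' Returns the significance/fold-change profile applied to each class:
#' circRNA uses raw p < 0.05 with fold change >= 2; miRNA uses
#' FDR < 0.05 with fold change >= 1.5; mRNA uses FDR < 0.05 with fold
#' change >= 2.
#'
#' @param class One of `"circ"`, `"mirna"`, `"mrna"`.
#' @return list with `alpha`, `fcMin`, `useFdr`.
#' @export
deProfile <- function(class = c("circ", "mirna", "mrna")) {
  switch(match.arg(class),
    circ = list(alpha = 0.05, fcMin = 2, useFdr = FALSE),
    mirna = list(alpha = 0.05, fcMin = 1.5, useFdr = TRUE),
    mrna = list(alpha = 0.05, fcMin = 2, useFdr = TRUE))
}

#' Classify differential-expression calls
#'
#' A feature is `up` iff its significance criterion (raw p or FDR) is below
#' `alpha` and `2^log2fc >= fcMin`; `down` symmetrically with
#' `2^-log2fc >= fcMin`; otherwise `ns`.
#'
#' @param results data.frame from [testTwoGroup()].
#' @param alpha Significance threshold.
#' @param fcMin Minimum fold change (>= 1).
#' @param useFdr Use the BH-adjusted `fdr` column instead of raw `p_value`.
#' @return `results` with a `direction` column added.
#' @export
classifyDE <- function(results, alpha = 0.05, fcMin = 2, useFdr = FALSE) {
  if (fcMin < 1) stop("fcMin must be >= 1")
  crit <- if (useFdr) results$fdr else results$p_value
  up <- crit < alpha & 2^results$log2fc >= fcMin
  down <- crit < alpha & 2^(-results$log2fc) >= fcMin
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

# all permutations of 1..n as an (n! x n) matrix, lexicographic
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank association
#'
#' Correlation of midranks (average ranks for ties). For `n <= exactN` the
#' two-sided p-value is exact, from complete enumeration of permutations of
#' one variable; otherwise the t approximation
#' `t = rho * sqrt((n - 2)/(1 - rho^2))` on `n - 2` df is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exactN Largest n for which the permutation null is enumerated.
#' @return list with `rho`, `p`, `n`, `method`, and `constant` flag (TRUE
#'   when either vector is constant, in which case rho is NA).
#' @export
spearmanAssoc <- function(x, y, exactN = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "none",
                constant = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exactN) {
    perms <- .permutations(n)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    mx <- mean(rx); my <- mean(ry)
    M <- matrix(ry[perms], nrow = nrow(perms))
    rhoPerm <- (M %*% rx / n - mx * my) * n / (n - 1) / (sx * sy)
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact",
                constant = FALSE))
  }
  r2 <- min(rho^2, 1 - 1e-12)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n, method = "t", constant = FALSE)
}

#' TPM-like normalization of a count matrix
#'
#' Column-scales counts to transcripts-per-million style values:
#' `1e6 * count / librarySize`. No length correction is applied (features
#' in toy annotation carry lengths only optionally); the values serve as an
#' expression filter, not as cross-feature abundance estimates.
#'
#' @param counts Matrix features x samples.
#' @param libSizes Per-sample library sizes; defaults to column sums.
#' @return Numeric matrix of the same shape.
#' @export
tpmFromCounts <- function(counts, libSizes = colSums(counts)) {
  if (any(libSizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2, libSizes, "/") * 1e6
}
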