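## MARS: the MA-plot-based differential-expression statistic under the
## random sampling (binomial) model, applied to ordered stage pairs.

#' MARS statistic for a two-library count comparison
#'
#' For counts C1, C2 with library totals n1, n2, computes
#' M = log2 C1 - log2 C2 and A = (log2 C1 + log2 C2)/2. Under the random
#' sampling model each count is binomial in its library total at a common
#' proportion; conditioning on A with estimate p = 2^A / sqrt(n1 n2), the
#' log ratio has mean E(M|A) = log2(n1/n2) and variance
#' Var(M|A) = 4 (1 - p) / ((n1 + n2) p ln^2 2). The standardized deviate
#' Z = (M - E(M|A)) / sqrt(Var(M|A)) is referred to the standard normal
#' for a two-sided p-value.
#'
#' When exactly one count is zero it is replaced by 0.5 before taking logs
#' and the row is flagged; when both are zero the gene is returned
#' non-significant with p = 1.
#'
#' @param c1,c2 raw counts (vectors).
#' @param n1,n2 library totals (mapped reads).
#' @return data.frame with C1, C2, M, A, pHat, Z, p, flagged.
#' @examples
#' marsTest(2000, 1000, 1e6, 1e6)
#' @export
marsTest <- function(c1, c2, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  k <- max(length(c1), length(c2))
  c1 <- rep(c1, length.out = k); c2 <- rep(c2, length.out = k)
  n1 <- rep(n1, length.out = k); n2 <- rep(n2, length.out = k)

  bothZero <- c1 == 0 & c2 == 0
  flagged <- xor(c1 == 0, c2 == 0)
  w1 <- ifelse(c1 == 0, 0.5, c1)
  w2 <- ifelse(c2 == 0, 0.5, c2)

  M <- log2(w1) - log2(w2)
  A <- (log2(w1) + log2(w2)) / 2
  pHat <- 2^A / sqrt(n1 * n2)
  if (any(pHat >= 1 & !bothZero)) stop("saturated proportion: pHat >= 1")
  varM <- 4 * (1 - pHat) / ((n1 + n2) * pHat * log(2)^2)
  Z <- (M - log2(n1 / n2)) / sqrt(varM)
  p <- 2 * pnorm(-abs(Z))
  Z[bothZero] <- 0
  p[bothZero] <- 1
  data.frame(C1 = c1, C2 = c2, M = M, A = A, pHat = pHat, Z = Z, p = p,
             flagged = flagged)
}

#' Compare two samples of an expression container with MARS
#'
#' Runs [marsTest()] on every feature for one ordered sample pair. The
#' sign convention follows the order: a positive significant Z means the
#' first sample is the higher one.
#'
#' @param x an [MztExperiment-class].
#' @param sample1,sample2 sample names (order matters).
#' @param alpha significance level (default 0.05; the study applies no
#'   multiple-testing correction).
#' @param adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return data.frame with feature, C1, C2, M, A, Z, p, significant,
#'   flagged.
#' @export
compareStages <- function(x, sample1, sample2, alpha = 0.05,
                          adjust = "none") {
  for (s in c(sample1, sample2))
    if (!s %in% colnames(x)) stop("unknown sample: ", s)
  cnt <- SummarizedExperiment::assay(x, "counts")
  lib <- SummarizedExperiment::colData(x)$libSize
  names(lib) <- colnames(x)
  res <- marsTest(cnt[, sample1], cnt[, sample2],
                  lib[sample1], lib[sample2])
  res$p <- stats::p.adjust(res$p, method = adjust)
  out <- cbind(data.frame(feature = rownames(x), stringsAsFactors = FALSE),
               res)
  out$significant <- out$p < alpha
  out
}

## The four canonical stage-pair comparisons of one ploidy, in the fixed
## order: oocyte vs 0-2 h, 0-2 h vs 0-6 h, oocyte vs 0-6 h, 0-6 h vs
## 18-24 h.
.stagePairs <- function(ploidy) {
  s <- ploidySamples(ploidy)
  list(oocyte_vs_0_2h = c(s[1], s[2]),
       x0_2h_vs_0_6h = c(s[2], s[3]),
       oocyte_vs_0_6h = c(s[1], s[3]),
       x0_6h_vs_18_24h = c(s[3], s[4]))
}

#' Run the four canonical stage comparisons for one ploidy
#'
#' Produces the comparison tables the MZT classifier consumes: oocyte vs
#' 0-2 h, 0-2 h vs 0-6 h, oocyte vs 0-6 h, and 0-6 h vs 18-24 h, each as
#' an ordered pair (first sample minus second on the M scale).
#'
#' @param x an [MztExperiment-class].
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param alpha significance level.
#' @param adjust p-value adjustment method (default `"none"`).
#' @return Named list of four [compareStages()] tables.
#' @export
canonicalComparisons <- function(x, ploidy = c("diploid", "haploid"),
                                 alpha = 0.05, adjust = "none") {
  ploidy <- match.arg(ploidy)
  lapply(.stagePairs(ploidy), function(pr)
    compareStages(x, pr[1], pr[2], alpha = alpha, adjust = adjust))
}
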