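#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over features with
#' all-positive counts, of the ratio of the sample's count to the
#' feature's geometric mean across samples. Falls back to total-count
#' scaling (normalized to geometric mean 1) with a warning when no
#' feature is positive everywhere.
#'
#' @param counts integer matrix, rows = features, columns = samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos)) {
    warning("no feature with all-positive counts; using total-count scaling",
            call. = FALSE)
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  logc <- log(counts[allpos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  exp(apply(logc - loggeo, 2, stats::median))
}

#' Simplified negative-binomial Wald test for differential abundance
#'
#' A DESeq2-style two-group test without dispersion or fold-change
#' shrinkage: median-of-ratios normalization, per-feature
#' method-of-moments dispersion pooled across the two groups (floored at
#' 1e-8), log2 fold change with a 0.5 pseudocount, a Wald statistic with
#' the standard error propagated from the NB variance, and a two-sided
#' p-value from a Student t reference with `n1 + n2 - 2` degrees of
#' freedom (the small-sample correction for the noise in the plug-in
#' dispersion; a normal reference is anti-conservative at triplicate
#' scale). Benjamini-Hochberg q-values are reported alongside, but the
#' significance flag follows the raw-p rule `wald_p < alpha`.
#'
#' @param counts integer matrix, rows = features, columns = samples.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels; the second level is "treated" in the fold change.
#' @param alpha raw-p significance threshold (default 0.01).
#' @param sf optional size factors (default [size_factors()]).
#' @return data.frame with one row per feature: `feature`, `baseMean`,
#'   `log2fc`, `se`, `wald_p`, `bh_q`, `significant`.
#' @export
nb_wald_test <- function(counts, condition, alpha = 0.01, sf = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2)
    stop("condition must have exactly two levels", call. = FALSE)
  if (any(table(condition) < 2))
    stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(y[, g1, drop = FALSE]); m2 <- rowMeans(y[, g2, drop = FALSE])
  v1 <- apply(y[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, g2, drop = FALSE], 1, stats::var)
  # pooled method-of-moments NB dispersion: var = mu + a mu^2
  disp <- pmax(((n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)) /
                 ((n1 - 1) * m1^2 + (n2 - 1) * m2^2), 1e-8)
  disp[!is.finite(disp)] <- 1e-8
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  se2 <- (m1 + disp * m1^2) / n1 / ((m1 + 0.5)^2 * log(2)^2) +
    (m2 + disp * m2^2) / n2 / ((m2 + 0.5)^2 * log(2)^2)
  se <- sqrt(se2)
  p <- 2 * stats::pt(-abs(log2fc / se), df = n1 + n2 - 2)
  zero <- m1 == 0 & m2 == 0
  log2fc[zero] <- 0; p[zero] <- 1; se[zero] <- NA_real_
  res <- data.frame(feature = rownames(counts),
                    baseMean = rowMeans(y),
                    log2fc = log2fc, se = se, wald_p = p,
                    bh_q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res$significant <- res$wald_p < alpha
  rownames(res) <- NULL
  res
}
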