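#' Marginal per-SNP regression scan
#'
#' Regresses the estimated per-line genomic values \eqn{\hat g} (from a
#' full-data GBLUP fit) on each SNP's allele count (0/2) separately and
#' tests the slope with a t-test on `n - 2` degrees of freedom. The scan
#' is vectorized through the correlation identity
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}. Monomorphic SNPs are skipped with
#' a warning and reported with `NA` statistics.
#'
#' @param g_hat named per-line numeric vector (names = line ids) or plain
#'   vector aligned to the panel's lines
#' @param panel a `genotype_panel` (complete genotypes; impute first if
#'   needed)
#' @return an object of class `marginal_result`: data.frame with columns
#'   `snp_id`, `chrom`, `pos`, `beta`, `t`, `p`, `n`
#' @export
marginal_scan <- function(g_hat, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- as.numeric(g_hat)
  if (!is.null(names(g_hat))) {
    if (!all(panel$line_ids %in% names(g_hat)))
      stopf("g_hat names do not cover the panel's lines")
    g <- as.numeric(g_hat[panel$line_ids])
  }
  if (length(g) != length(panel$line_ids)) stopf("g_hat not aligned to panel lines")
  A <- panel$geno
  if (anyNA(A)) stopf("panel has missing genotypes; run impute_genotypes() first")
  n <- nrow(A)
  if (n < 3) stopf("need at least 3 lines")
  gc_ <- g - mean(g)
  Ac <- sweep(A, 2, colMeans(A), "-")
  sxx <- colSums(Ac^2)
  mono <- sxx <= .Machine$double.eps
  if (any(mono))
    warning(sprintf("%d monomorphic SNP(s) skipped in marginal scan", sum(mono)),
            call. = FALSE)
  sxy <- as.numeric(crossprod(Ac, gc_))
  syy <- sum(gc_^2)
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  r2 <- ifelse(mono | syy == 0, NA_real_, sxy^2 / (sxx * syy))
  r2 <- pmin(r2, 1)
  tstat <- sign(beta) * sqrt(r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  res <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                    pos = panel$map$pos, beta = beta, t = tstat, p = pval,
                    n = n)
  class(res) <- c("marginal_result", "data.frame")
  res
}

#' Genome-wide Bonferroni significance threshold
#'
#' @param m_snps number of tests
#' @param alpha family-wise error rate (default 0.05)
#' @return the per-test threshold `alpha / m_snps`
#' @export
genomewide_threshold <- function(m_snps, alpha = 0.05) {
  if (m_snps < 1) stopf("m_snps must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  alpha / m_snps
}
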