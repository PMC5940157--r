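#' SNP filter specification
#'
#' Thresholds of the standard inbred-panel SNP filter: minor allele
#' frequency at least `maf_min` (inclusive), Phred quality strictly above
#' `qual_min`, and genotype call rate at least `callrate_min` (inclusive).
#'
#' @param maf_min minimum minor-allele frequency, inclusive (default 0.05)
#' @param qual_min Phred quality threshold, strict `>` (default 500)
#' @param callrate_min minimum call rate, inclusive (default 0.8)
#' @return an object of class `snp_filter_spec`
#' @export
snp_filter_spec <- function(maf_min = 0.05, qual_min = 500, callrate_min = 0.8) {
  if (maf_min < 0 || maf_min > 0.5) stopf("maf_min must be in [0, 0.5]")
  if (callrate_min < 0 || callrate_min > 1) stopf("callrate_min must be in [0, 1]")
  structure(list(maf_min = maf_min, qual_min = qual_min,
                 callrate_min = callrate_min),
            class = "snp_filter_spec")
}

#' Filter SNPs on MAF, Phred quality, and call rate
#'
#' Retains SNPs with `maf >= maf_min`, `qual > qual_min` and
#' `call_rate >= callrate_min`, preserving order. SNPs failing several
#' criteria are attributed, for reporting only, to the first failing
#' criterion in the order MAF, quality, call rate. SNPs with no quality
#' score recorded are not removed on quality.
#'
#' @param panel a `genotype_panel`
#' @param spec an `snp_filter_spec`
#' @return the filtered `genotype_panel`, with attribute `filter_report`
#'   (data.frame of per-criterion removal counts). An empty result is
#'   allowed and reported.
#' @export
filter_snps <- function(panel, spec = snp_filter_spec()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(spec, "snp_filter_spec"))
  m <- panel$map
  fail_maf <- m$maf < spec$maf_min
  fail_qual <- !is.na(m$qual) & m$qual <= spec$qual_min
  fail_cr <- m$call_rate < spec$callrate_min
  # first-failing-criterion attribution
  why <- rep(NA_character_, nrow(m))
  why[fail_cr] <- "call_rate"
  why[fail_qual] <- "quality"
  why[fail_maf] <- "maf"
  keep <- is.na(why)
  report <- data.frame(
    criterion = c("maf", "quality", "call_rate", "retained"),
    n = c(sum(why == "maf", na.rm = TRUE), sum(why == "quality", na.rm = TRUE),
          sum(why == "call_rate", na.rm = TRUE), sum(keep)))
  msgf("filter_snps: retained %d of %d SNPs (removed maf=%d, quality=%d, call_rate=%d)",
       sum(keep), nrow(m), report$n[1], report$n[2], report$n[3])
  if (!any(keep)) {
    out <- panel
    out$geno <- panel$geno[, 0, drop = FALSE]
    out$map <- panel$map[0, , drop = FALSE]
  } else {
    out <- subset_snps(panel, which(keep))
  }
  attr(out, "filter_report") <- report
  out
}
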