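#' Construct a genotype panel of fully inbred lines
#'
#' A genotype panel holds the allele-count matrix of a set of fully
#' homozygous lines (entries 0 or 2, counting minor alleles; `NA` allowed
#' before filtering/imputation) together with per-SNP metadata. Columns are
#' re-oriented so that the counted allele is the minor allele; ties at
#' frequency 0.5 keep the orientation as supplied.
#'
#' @param geno numeric matrix, lines x SNPs, entries in \{0, 2, NA\}.
#' @param map data.frame with one row per SNP: columns `snp_id`, `chrom`,
#'   `pos` (1-based bp, strictly increasing within chromosome), and
#'   optionally `qual` (Phred score), `call_rate`. Minor-allele frequency
#'   and call rate are always (re)computed from `geno`.
#' @param line_ids character vector of line labels; defaults to
#'   `rownames(geno)` or `L001...`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `geno` (oriented allele counts), `map` (metadata incl. `maf`,
#'   `call_rate`), `line_ids`.
#' @export
genotype_panel <- function(geno, map, line_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (!all(geno %in% c(0, 2) | is.na(geno)))
    stopf("allele counts must be 0 or 2 (fully homozygous lines); got other values")
  if (nrow(map) != ncol(geno))
    stopf("map has %d rows but geno has %d SNP columns", nrow(map), ncol(geno))
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stopf("map must contain columns %s", paste(need, collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  if (anyDuplicated(map$snp_id)) stopf("duplicated snp_id in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stopf("positions must strictly increase within chromosome %s", ch)
  }
  if (is.null(line_ids)) line_ids <- rownames(geno)
  if (is.null(line_ids)) line_ids <- sprintf("L%03d", seq_len(nrow(geno)))
  line_ids <- as.character(line_ids)
  if (length(line_ids) != nrow(geno)) stopf("line_ids length mismatch")
  rownames(geno) <- line_ids
  colnames(geno) <- map$snp_id

  # minor-allele orientation: flip columns whose counted-allele frequency
  # exceeds 0.5; ties at 0.5 keep the supplied orientation
  freq <- colMeans(geno, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) geno[, flip] <- 2 - geno[, flip]
  map$maf <- colMeans(geno, na.rm = TRUE) / 2
  map$call_rate <- colMeans(!is.na(geno))
  if (!"qual" %in% names(map)) map$qual <- NA_real_

  structure(list(geno = geno, map = map, line_ids = line_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d lines x %d SNPs on %d chromosome(s)\n",
              length(x$line_ids), nrow(x$map), length(unique(x$map$chrom))))
  cat(sprintf("  MAF range: %.3f-%.3f; missing entries: %d\n",
              min(x$map$maf), max(x$map$maf), sum(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a panel to a set of SNP columns (order preserved as given)
#' @param panel a `genotype_panel`
#' @param snp_idx integer column indices to keep
#' @return a `genotype_panel`
#' @export
subset_snps <- function(panel, snp_idx) {
  stopifnot(inherits(panel, "genotype_panel"))
  snp_idx <- as.integer(snp_idx)
  if (length(snp_idx) == 0) stopf("empty SNP subset")
  if (any(snp_idx < 1 | snp_idx > ncol(panel$geno))) stopf("SNP index out of range")
  genotype_panel(panel$geno[, snp_idx, drop = FALSE],
                 panel$map[snp_idx, c("snp_id", "chrom", "pos", "qual"), drop = FALSE],
                 panel$line_ids)
}

#' Mean-impute missing genotypes
#'
#' Missing allele counts are replaced by the per-SNP mean of the observed
#' counts (a value in `[0, 2]`, not forced back onto \{0, 2\}), so that the
#' centered genotype matrix keeps zero column means. Intended to run after
#' SNP filtering and before any matrix algebra.
#'
#' @param panel a `genotype_panel`
#' @return the panel with `geno` complete
#' @export
impute_genotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  nas <- which(is.na(g), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(g, na.rm = TRUE)
    g[nas] <- mu[nas[, 2]]
    panel$geno <- g
  }
  panel
}
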