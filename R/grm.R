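#' Center and scale an allele-count matrix
#'
#' Each retained column i of the allele-count matrix is standardized as
#' \eqn{w_i = (a_i - 2 p_i) / \sqrt{2 p_i (1 - p_i)}}, where \eqn{p_i} is
#' the within-panel frequency of the counted allele
#' (\eqn{p_i = \bar a_i / 2}; on a minor-oriented panel this is the minor
#' allele frequency). Columns therefore have exactly zero mean. Missing
#' genotypes, if still present, are mean-imputed first (see
#' [impute_genotypes()]).
#'
#' @param panel a `genotype_panel`
#' @param snp_subset optional integer vector of panel SNP columns to use
#'   (default: all)
#' @return an object of class `scaled_genotypes`: list with `W` (lines x
#'   SNPs standardized matrix), `snp_index` (panel column indices),
#'   `m` (SNP count), `line_ids`.
#' @export
center_scale <- function(panel, snp_subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- if (is.null(snp_subset)) seq_len(ncol(panel$geno)) else as.integer(snp_subset)
  if (length(idx) == 0) stopf("empty SNP subset")
  A <- panel$geno[, idx, drop = FALSE]
  if (anyNA(A)) {
    mu <- colMeans(A, na.rm = TRUE)
    nas <- which(is.na(A), arr.ind = TRUE)
    A[nas] <- mu[nas[, 2]]
  }
  p <- colMeans(A) / 2
  mono <- p * (1 - p) <= 0
  if (any(mono))
    stopf("monomorphic SNP(s) in subset cannot be scaled: %s",
          paste(utils::head(panel$map$snp_id[idx][mono], 5), collapse = ", "))
  W <- sweep(A, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  structure(list(W = W, snp_index = idx, m = length(idx),
                 line_ids = panel$line_ids),
            class = "scaled_genotypes")
}

#' Compute a genomic relationship matrix G = WW'/m
#'
#' @param Wm a `scaled_genotypes` object
#' @param label one of `"total"`, `"feature"`, `"remainder"`
#' @return an object of class `grm`: list with `G` (symmetric line x line
#'   matrix), `m` (SNP count used), `label`, `line_ids`.
#' @export
compute_grm <- function(Wm, label = "total") {
  stopifnot(inherits(Wm, "scaled_genotypes"))
  label <- match.arg(label, c("total", "feature", "remainder"))
  G <- tcrossprod(Wm$W) / Wm$m
  dimnames(G) <- list(Wm$line_ids, Wm$line_ids)
  structure(list(G = G, m = Wm$m, label = label, line_ids = Wm$line_ids),
            class = "grm")
}

#' Partition a GRM into feature and remainder components
#'
#' Splits the columns of the scaled genotype matrix into the feature set f
#' and its complement r, and returns \eqn{G_f = W_f W_f'/m_f} and
#' \eqn{G_r = W_r W_r'/m_r}. The exact reconstruction identity
#' \eqn{m_f G_f + m_r G_r = m G} holds by additivity of outer products.
#'
#' @param Wm a `scaled_genotypes` object for all m SNPs
#' @param feature_snps panel SNP column indices of the feature set; must be
#'   a nonempty strict subset of `Wm$snp_index`
#' @return list with elements `feature` and `remainder`, both `grm` objects
#' @export
partition_grm <- function(Wm, feature_snps) {
  stopifnot(inherits(Wm, "scaled_genotypes"))
  feature_snps <- unique(as.integer(feature_snps))
  inf <- Wm$snp_index %in% feature_snps
  if (!any(inf)) stopf("feature SNP set is empty within the scaled matrix")
  if (all(inf)) stopf("feature SNP set covers all SNPs; a two-component model needs a nonempty remainder")
  Wf <- structure(list(W = Wm$W[, inf, drop = FALSE],
                       snp_index = Wm$snp_index[inf], m = sum(inf),
                       line_ids = Wm$line_ids), class = "scaled_genotypes")
  Wr <- structure(list(W = Wm$W[, !inf, drop = FALSE],
                       snp_index = Wm$snp_index[!inf], m = sum(!inf),
                       line_ids = Wm$line_ids), class = "scaled_genotypes")
  list(feature = compute_grm(Wf, "feature"), remainder = compute_grm(Wr, "remainder"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d lines, m = %d SNPs, mean diagonal %.3f\n",
              x$label, nrow(x$G), x$m, mean(diag(x$G))))
  invisible(x)
}

#' Write a GRM as TSV with a JSON metadata sidecar
#'
#' The matrix is written with line ids as header and row names; a sidecar
#' `<path>.meta.json` records `m` and `label`.
#'
#' @param grm a `grm` object
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  df <- data.frame(line_id = grm$line_ids, grm$G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(m = grm$m, label = grm$label),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path TSV path
#' @return a `grm` object
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$line_id
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  structure(list(G = G, m = meta$m, label = meta$label, line_ids = df$line_id),
            class = "grm")
}
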