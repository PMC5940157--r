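#' Map SNPs to gene intervals
#'
#' A SNP belongs to a gene when it lies on the same chromosome with
#' `start <= pos <= end` (intervals are 1-based, inclusive on both ends).
#' A SNP may belong to several overlapping genes. Intervals on chromosomes
#' absent from the panel are skipped with a warning.
#'
#' @param panel a `genotype_panel`
#' @param gene_intervals data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive)
#' @return a `feature_map`: list with `gene_to_snps` (named list of panel
#'   SNP column indices, genome order), `genes` (the interval table),
#'   `go_to_genes`/`go_to_snps` (empty until [aggregate_genes_to_go()])
#' @export
map_snps_to_genes <- function(panel, gene_intervals) {
  stopifnot(inherits(panel, "genotype_panel"))
  gi <- as.data.frame(gene_intervals, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(gi)))
    stopf("gene_intervals must contain columns %s", paste(need, collapse = ", "))
  gi$gene_id <- as.character(gi$gene_id)
  gi$chrom <- as.character(gi$chrom)
  unknown <- !(gi$chrom %in% unique(panel$map$chrom))
  if (any(unknown)) {
    warning(sprintf("%d gene interval(s) on chromosomes absent from the panel were skipped",
                    sum(unknown)), call. = FALSE)
    gi <- gi[!unknown, , drop = FALSE]
  }
  snp_gr <- GenomicRanges::GRanges(panel$map$chrom,
                                   IRanges::IRanges(panel$map$pos, panel$map$pos))
  gene_to_snps <- stats::setNames(vector("list", nrow(gi)), gi$gene_id)
  if (nrow(gi) > 0) {
    gene_gr <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start, gi$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
    sh <- S4Vectors::queryHits(hits)
    gh <- S4Vectors::subjectHits(hits)
    for (j in seq_len(nrow(gi)))
      gene_to_snps[[j]] <- sort(sh[gh == j])
  }
  structure(list(gene_to_snps = gene_to_snps, genes = gi,
                 go_to_genes = list(), go_to_snps = list()),
            class = "feature_map")
}

#' Aggregate genes into GO-term SNP sets
#'
#' Populates the GO level of a feature map: each term's SNP set is the
#' de-duplicated union of its member genes' SNPs, kept in genome order.
#' Terms whose genes contribute no panel SNPs are dropped with a message.
#'
#' @param fmap a `feature_map` from [map_snps_to_genes()]
#' @param go_table data.frame with columns `gene_id`, `go_id`
#' @return the `feature_map` with `go_to_genes` and `go_to_snps` filled
#' @export
aggregate_genes_to_go <- function(fmap, go_table) {
  stopifnot(inherits(fmap, "feature_map"))
  gt <- as.data.frame(go_table, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_id") %in% names(gt)))
    stopf("go_table must contain columns gene_id, go_id")
  gt$gene_id <- as.character(gt$gene_id)
  gt$go_id <- as.character(gt$go_id)
  terms <- sort(unique(gt$go_id))
  go_to_genes <- list(); go_to_snps <- list()
  dropped <- character(0)
  for (tm in terms) {
    genes <- sort(unique(gt$gene_id[gt$go_id == tm]))
    genes <- genes[genes %in% names(fmap$gene_to_snps)]
    snps <- sort(unique(unlist(fmap$gene_to_snps[genes], use.names = FALSE)))
    if (length(snps) == 0) { dropped <- c(dropped, tm); next }
    go_to_genes[[tm]] <- genes
    go_to_snps[[tm]] <- snps
  }
  if (length(dropped) > 0)
    msgf("aggregate_genes_to_go: dropped %d GO term(s) with no mapped SNPs (%s)",
         length(dropped), paste(dropped, collapse = ", "))
  fmap$go_to_genes <- go_to_genes
  fmap$go_to_snps <- go_to_snps
  fmap
}

#' @export
print.feature_map <- function(x, ...) {
  n_in <- length(unique(unlist(x$gene_to_snps, use.names = FALSE)))
  cat(sprintf("feature_map: %d genes (%d SNPs in genes), %d GO terms\n",
              length(x$gene_to_snps), n_in, length(x$go_to_snps)))
  invisible(x)
}
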