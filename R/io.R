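#' @name panel_io
#' @title Readers and writers for panels, annotations and phenotypes
#'
#' @description
#' Genotype panels round-trip through VCF (homozygous diploid GT fields,
#' `0/0` or `1/1`) or a TSV line x SNP allele-count matrix with a
#' `<path>.snps.tsv` metadata sidecar; gene intervals through BED
#' (0-based half-open on disk, converted to 1-based inclusive in memory)
#' or GFF3; GO membership and phenotypes through plain TSV/CSV.
NULL

#' Write a genotype panel as VCF
#'
#' Sites are biallelic with placeholder REF/ALT alleles; the ALT allele is
#' the counted (minor) allele, so allele count 0 maps to GT `0/0` and 2 to
#' `1/1`; missing genotypes become `./.`.
#'
#' @param panel a `genotype_panel`
#' @param path output path (plain text `.vcf`)
#' @return `path`, invisibly
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gfblup simulate",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$line_ids), collapse = "\t")), con)
  gt <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
  gt[panel$geno == 0] <- "0/0"
  gt[panel$geno == 2] <- "1/1"
  body <- cbind(panel$map$chrom, panel$map$pos, panel$map$snp_id, "A", "T",
                ifelse(is.na(panel$map$qual), ".", panel$map$qual), "PASS",
                ".", "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a genotype panel as a TSV allele-count matrix
#'
#' Writes the line x SNP matrix with a `line_id` column, plus a
#' `<path>.snps.tsv` sidecar holding the SNP metadata so that the panel
#' round-trips exactly through [read_genotypes()].
#'
#' @param panel a `genotype_panel`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(line_id = panel$line_ids, panel$geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map[, c("snp_id", "chrom", "pos", "qual")],
                     paste0(path, ".snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from VCF or TSV
#'
#' VCF: biallelic sites with fully homozygous calls are kept; sites with
#' any heterozygous call or multiple ALT alleles are dropped with a
#' logged count. Genotypes are ALT-allele counts (`0/0` -> 0, `1/1` -> 2,
#' `./.` -> missing), re-oriented to the minor allele per site; MAF and
#' call rate are computed from the data. TSV: the format written by
#' [write_panel_tsv()] (the metadata sidecar is used when present;
#' otherwise SNPs are placed consecutively on one chromosome).
#'
#' @param path input file
#' @param format `"vcf"` or `"tsv"`
#' @return a `genotype_panel`
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    geno <- as.matrix(df[, -1, drop = FALSE])
    side <- paste0(path, ".snps.tsv")
    map <- if (file.exists(side)) {
      utils::read.table(side, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
    } else {
      data.frame(snp_id = colnames(geno), chrom = "1",
                 pos = seq_len(ncol(geno)), qual = NA_real_)
    }
    if (ncol(geno) == 0) stopf("no usable SNPs in %s", path)
    return(genotype_panel(geno, map, line_ids = df[[1]]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stopf("no usable SNPs in %s", path)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gsub("|", "/", gt_raw, fixed = TRUE)
  count <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw))
  count[gt_raw == "0/0"] <- 0
  count[gt_raw == "1/1"] <- 2
  het <- gt_raw %in% c("0/1", "1/0")
  bad_het <- rowSums(matrix(het, nrow(gt_raw))) > 0
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  drop <- bad_het | multi
  if (any(drop))
    msgf("read_genotypes: dropped %d site(s) (%d heterozygous, %d multi-allelic)",
         sum(drop), sum(bad_het), sum(multi & !bad_het))
  if (all(drop)) stopf("no usable SNPs in %s", path)
  keep <- !drop
  map <- data.frame(snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                                    paste0(fix$CHROM[keep], ":", fix$POS[keep]),
                                    fix$ID[keep]),
                    chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    qual = suppressWarnings(as.numeric(fix$QUAL[keep])))
  genotype_panel(t(count[keep, , drop = FALSE]), map,
                 line_ids = colnames(gt_raw))
}

#' Write gene intervals as BED
#'
#' In-memory intervals are 1-based inclusive; BED is written 0-based
#' half-open (`start - 1`, `end`).
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#' @param path output BED path
#' @return `path`, invisibly
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED, GFF3 or TSV
#'
#' BED and GFF3 are parsed with \pkg{rtracklayer} (BED's 0-based
#' half-open coordinates become 1-based inclusive); TSV expects the
#' columns `gene_id`, `chrom`, `start`, `end` already 1-based inclusive.
#'
#' @param path input file
#' @param format `"bed"`, `"gff3"` or `"tsv"`
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`
#' @export
read_gene_intervals <- function(path, format = c("bed", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character")))
  }
  gr <- rtracklayer::import(path, format = format)
  ids <- if (format == "bed") gr$name else
    (gr$ID %||% gr$Name %||% as.character(seq_along(gr)))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write / read a two-column gene-to-GO membership table
#' @param go_table data.frame with `gene_id`, `go_id`
#' @param path TSV path
#' @return `path` (write) or the table (read)
#' @export
write_go_tsv <- function(go_table, path) {
  utils::write.table(go_table[, c("gene_id", "go_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_tsv
#' @export
read_go_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read replicated phenotype records as CSV
#' @param pheno data.frame with columns `line_id`, `replicate`, `day`,
#'   `block`, `plate`, `value`
#' @param path CSV path
#' @return `path` (write) or the table (read)
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(line_id = "character"))
}

#' Write simulation truth (causal effects and per-line genomic values)
#' @param truth the `truth` element of [simulate_phenotypes()]
#' @param path TSV path prefix; writes `<path>` (per-line values) and
#'   `<path>.effects.tsv` (per-causal-SNP effects)
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(truth, path) {
  lines <- data.frame(line_id = names(truth$g_total),
                      g_f = as.numeric(truth$g_f),
                      g_r = as.numeric(truth$g_r),
                      g_total = as.numeric(truth$g_total))
  utils::write.table(lines, path, sep = "\t", quote = FALSE, row.names = FALSE)
  eff <- rbind(
    data.frame(component = "feature", snp_id = names(truth$effects_f),
               effect = as.numeric(truth$effects_f)),
    data.frame(component = "remainder", snp_id = names(truth$effects_r),
               effect = as.numeric(truth$effects_r)))
  utils::write.table(eff, paste0(path, ".effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation config from a JSON file
#'
#' The file may contain any subset of [sim_config()]'s arguments; absent
#' fields take the defaults.
#'
#' @param path JSON path
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$chrom_layout)) args$chrom_layout <-
    stats::setNames(as.integer(args$chrom_layout), names(args$chrom_layout))
  if (!is.null(args$architecture)) args$architecture <- as.list(args$architecture)
  if (!is.null(args$maf_spectrum)) args$maf_spectrum <- as.list(args$maf_spectrum)
  do.call(sim_config, args)
}
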