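#' Configuration for the inbred-panel simulator
#'
#' Defines the study conditions the generator emulates: a panel of fully
#' inbred (homozygous) lines genotyped at biallelic SNPs spread over
#' chromosome arms, genes tiled over the chromosomes and aggregated into
#' GO terms, and a feature-enriched additive architecture with replicated
#' phenotype records under day/block/plate nuisance effects.
#'
#' @param n_lines number of inbred lines (default 200)
#' @param n_snps total number of SNPs (default 5000)
#' @param chrom_layout named integer vector of SNPs per chromosome; the
#'   default splits `n_snps` over the arms 2L, 2R, 3L, 3R, X (24% each)
#'   and 4 (4%)
#' @param maf_spectrum distribution of per-SNP sampling allele
#'   frequencies: `list(dist = "uniform", min, max)` (default
#'   uniform on `[0.05, 0.5]`) or `list(dist = "fixed", value)`; all mass
#'   must lie in `(0, 0.5]`
#' @param n_genes number of non-overlapping gene intervals (default 100)
#' @param gene_coverage fraction of SNPs lying inside genes (default 0.7)
#' @param genes_per_go mean number of genes drawn per GO term (Poisson,
#'   minimum 1; default 6)
#' @param n_go_terms number of GO terms (default 10)
#' @param architecture list with `feature_go` (term label carrying the
#'   enrichment, default `"GO:0001"`), variance fractions `sigma2_f`,
#'   `sigma2_r`, `sigma2_e` summing to 1, and optionally `n_causal_f`,
#'   `n_causal_r` (default: every SNP of the component is causal) and
#'   `causal_gene` (`TRUE` to concentrate all feature causals in the
#'   term's largest gene)
#' @param replicates_per_line phenotype records per line (default 23)
#' @param n_days,n_blocks,n_plates numbers of nuisance-factor levels
#'   (defaults 6, 4, 8)
#' @param fixed_effect_sd SD of the per-level fixed effects, phenotype
#'   units (default 0.25)
#' @param ld_blocks `NULL` for independent SNPs (default), or
#'   `list(block_size, n_founders, mutation)` for block-LD genotypes in
#'   which lines copy founder haplotype blocks
#' @param seed integer master seed; panel, annotation and phenotypes use
#'   `seed`, `seed + 1`, `seed + 2`
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_lines = 200, n_snps = 5000, chrom_layout = NULL,
                       maf_spectrum = list(dist = "uniform", min = 0.05, max = 0.5),
                       n_genes = 100, gene_coverage = 0.7,
                       genes_per_go = 6, n_go_terms = 10,
                       architecture = list(feature_go = "GO:0001",
                                           sigma2_f = 0.3, sigma2_r = 0.2,
                                           sigma2_e = 0.5),
                       replicates_per_line = 23,
                       n_days = 6, n_blocks = 4, n_plates = 8,
                       fixed_effect_sd = 0.25, ld_blocks = NULL, seed = 1) {
  if (is.null(chrom_layout)) {
    arms <- c("2L" = 0.24, "2R" = 0.24, "3L" = 0.24, "3R" = 0.24,
              "4" = 0.04, "X" = 0.24)
    # largest-remainder split: nonnegative counts that sum exactly to n_snps
    chrom_layout <- diff(c(0L, as.integer(round(cumsum(arms / sum(arms)) * n_snps))))
    names(chrom_layout) <- names(arms)
    chrom_layout <- chrom_layout[chrom_layout > 0]
  }
  if (sum(chrom_layout) != n_snps) stopf("chrom_layout must sum to n_snps")
  cnts <- c(n_lines = n_lines, n_snps = n_snps, n_genes = n_genes,
            n_go_terms = n_go_terms, replicates_per_line = replicates_per_line,
            n_days = n_days, n_blocks = n_blocks, n_plates = n_plates)
  if (any(cnts < 1)) stopf("all counts must be >= 1 (%s)",
                           paste(names(cnts)[cnts < 1], collapse = ", "))
  sp <- maf_spectrum
  ok <- switch(sp$dist %||% "",
               uniform = sp$min > 0 && sp$max <= 0.5 && sp$min <= sp$max,
               fixed = sp$value > 0 && sp$value <= 0.5,
               FALSE)
  if (!isTRUE(ok))
    stopf("invalid maf_spectrum: all mass must lie in (0, 0.5] (dist uniform or fixed)")
  a <- architecture
  a$feature_go <- a$feature_go %||% "GO:0001"
  fr <- c(a$sigma2_f, a$sigma2_r, a$sigma2_e)
  if (length(fr) != 3 || any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stopf("architecture variance fractions must be nonnegative and sum to 1")
  a$causal_gene <- isTRUE(a$causal_gene)
  if (gene_coverage <= 0 || gene_coverage >= 1) stopf("gene_coverage must be in (0,1)")
  structure(list(n_lines = n_lines, n_snps = n_snps, chrom_layout = chrom_layout,
                 maf_spectrum = sp, n_genes = n_genes,
                 gene_coverage = gene_coverage, genes_per_go = genes_per_go,
                 n_go_terms = n_go_terms, architecture = a,
                 replicates_per_line = replicates_per_line,
                 n_days = n_days, n_blocks = n_blocks, n_plates = n_plates,
                 fixed_effect_sd = fixed_effect_sd, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_maf <- function(sp, n) {
  switch(sp$dist,
         uniform = stats::runif(n, sp$min, sp$max),
         fixed = rep(sp$value, n))
}

#' Simulate a homozygous-line genotype panel
#'
#' Genotypes are allele counts in \{0, 2\}. Without LD, each SNP is drawn
#' independently with its sampling frequency from the MAF spectrum;
#' monomorphic draws are rejected and redrawn so every SNP segregates. In
#' block-LD mode, lines copy whole founder haplotype blocks (with a small
#' mutation rate), producing serially correlated SNPs. Positions increase
#' strictly within each chromosome; Phred-style quality scores and call
#' rates are attached as metadata. The same config yields a bit-identical
#' panel.
#'
#' @param config a [sim_config()]
#' @return a `genotype_panel`
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_lines
    m <- config$n_snps
    draw_col <- function(p) {
      for (t in 1:200) {
        a <- 2 * (stats::runif(n) < p)
        if (stats::var(a) > 0) return(a)
      }
      stopf("could not draw a polymorphic SNP at frequency %.3g with %d lines", p, n)
    }
    maf <- draw_maf(config$maf_spectrum, m)
    if (is.null(config$ld_blocks)) {
      geno <- vapply(maf, draw_col, numeric(n))
    } else {
      lb <- config$ld_blocks
      bs <- lb$block_size %||% 25
      nf <- lb$n_founders %||% 8
      mu <- lb$mutation %||% 0.02
      geno <- matrix(0, n, m)
      start <- 1
      for (mc in config$chrom_layout) {
        idx <- start:(start + mc - 1)
        blocks <- split(idx, ceiling(seq_along(idx) / bs))
        for (bl in blocks) {
          draw_founder_col <- function(p) {
            for (t in 1:200) {
              x <- 2 * (stats::runif(nf) < p)
              if (stats::var(x) > 0) return(x)
            }
            i <- sample(nf, 1)
            x[i] <- 2 - x[i]
            x
          }
          founders <- vapply(maf[bl], draw_founder_col, numeric(nf))
          pick <- sample(nf, n, replace = TRUE)
          gb <- founders[pick, , drop = FALSE]
          flip <- matrix(stats::runif(length(gb)) < mu, nrow(gb))
          gb[flip] <- 2 - gb[flip]
          geno[, bl] <- gb
        }
        start <- start + mc
      }
      # guarantee segregation after founder copying
      mono <- which(apply(geno, 2, stats::var) == 0)
      for (j in mono) {
        i <- sample(n, 1)
        geno[i, j] <- 2 - geno[i, j]
      }
    }
    chrom <- rep(names(config$chrom_layout), config$chrom_layout)
    pos <- unlist(lapply(config$chrom_layout, function(mc)
      cumsum(sample(100:10000, mc, replace = TRUE))), use.names = FALSE)
    map <- data.frame(snp_id = sprintf("snp_%05d", seq_len(m)),
                      chrom = chrom, pos = pos,
                      qual = round(stats::runif(m, 600, 3000)))
    genotype_panel(geno, map)
  })
}

#' Simulate gene intervals and GO membership over a panel
#'
#' Non-overlapping gene intervals are tiled over each chromosome so that
#' roughly `gene_coverage` of its SNPs fall inside genes, with gaps
#' left between and around genes (so some SNPs are intergenic). Each GO
#' term draws a Poisson-distributed number of member genes (minimum 1);
#' a gene may belong to several terms.
#'
#' @param panel a `genotype_panel`
#' @param config a [sim_config()]
#' @return a `feature_map` with GO level populated; the raw tables are
#'   available as `$genes` and `$go_table`
#' @export
simulate_annotation <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    counts <- table(factor(panel$map$chrom, levels = unique(panel$map$chrom)))
    n_genes <- config$n_genes
    if (n_genes > floor(sum(counts) * config$gene_coverage))
      stopf("n_genes = %d too large for %d SNP positions at coverage %.2f",
            n_genes, sum(counts), config$gene_coverage)
    # per-chromosome capacity: each gene needs >= 1 SNP and the layout must
    # keep n_in >= n_genes_c with at least one intergenic SNP
    cnt <- as.integer(counts)
    cap <- pmin(floor(config$gene_coverage * cnt), (cnt - 1L) %/% 2L)
    cap <- pmax(cap, 0L)
    if (sum(cap) < n_genes)
      stopf("n_genes = %d too large for %d SNP positions at coverage %.2f",
            n_genes, sum(cnt), config$gene_coverage)
    gshare <- integer(length(cnt))
    for (i in seq_len(n_genes)) {
      open <- which(gshare < cap)
      pick <- open[which.max(cnt[open] / (gshare[open] + 1))]
      gshare[pick] <- gshare[pick] + 1L
    }
    genes <- list(); gid <- 0
    for (ci in seq_along(counts)) {
      mc <- as.integer(counts[ci]); gc_ <- gshare[ci]
      if (gc_ < 1) next
      chrom_idx <- which(panel$map$chrom == names(counts)[ci])
      n_in <- min(floor(config$gene_coverage * mc), mc - gc_ - 1)
      if (n_in < gc_) stopf("n_genes too large on chromosome %s", names(counts)[ci])
      sizes <- rep(n_in %/% gc_, gc_)
      extra <- n_in - sum(sizes)
      if (extra > 0) {
        ei <- sample(gc_, extra)
        sizes[ei] <- sizes[ei] + 1
      }
      # distribute the remaining SNPs into gc_+1 gaps (ends included)
      n_gap <- mc - sum(sizes)
      cuts <- sort(sample(0:n_gap, gc_, replace = TRUE))
      gaps <- diff(c(0, cuts, n_gap))
      cursor <- 0
      for (g in seq_len(gc_)) {
        cursor <- cursor + gaps[g]
        first <- cursor + 1; last <- cursor + sizes[g]
        cursor <- last
        gid <- gid + 1
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene_%04d", gid),
          chrom = names(counts)[ci],
          start = panel$map$pos[chrom_idx[first]],
          end = panel$map$pos[chrom_idx[last]])
      }
    }
    genes <- do.call(rbind, genes)
    mean_gpt <- if (is.list(config$genes_per_go)) config$genes_per_go$mean
                else config$genes_per_go
    go_rows <- list()
    for (t in seq_len(config$n_go_terms)) {
      ng <- max(1, min(nrow(genes), stats::rpois(1, mean_gpt)))
      members <- sample(genes$gene_id, ng)
      go_rows[[t]] <- data.frame(gene_id = members,
                                 go_id = sprintf("GO:%04d", t))
    }
    go_table <- do.call(rbind, go_rows)
    fmap <- map_snps_to_genes(panel, genes)
    fmap <- aggregate_genes_to_go(fmap, go_table)
    fmap$go_table <- go_table
    fmap
  })
}

#' Simulate replicated phenotypes under a feature-enriched architecture
#'
#' The phenotype of record j of line i is
#' `value = d(day) + b(block) + p(plate) + g_f(i) + g_r(i) + e(ij)`.
#' Causal effects are drawn standard-Gaussian on the causal SNPs of each
#' genomic component and rescaled so the realized (in-sample) variances of
#' `g_f`, `g_r` and `e` hit the configured fractions exactly; day, block
#' and plate levels are assigned at random per record with level effects
#' drawn once from `N(0, fixed_effect_sd^2)`.
#'
#' @param panel a `genotype_panel`
#' @param fmap a `feature_map` containing the architecture's GO term
#' @param config a [sim_config()]
#' @return list with `pheno` (data.frame `line_id`, `replicate`, `day`,
#'   `block`, `plate`, `value`) and `truth` (causal SNP ids and effects
#'   per component, per-line genomic values, realized variance fractions,
#'   fixed-effect level values, and the designated causal gene if any)
#' @export
simulate_phenotypes <- function(panel, fmap, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(fmap, "feature_map"),
            inherits(config, "sim_config"))
  a <- config$architecture
  feat_snps <- fmap$go_to_snps[[a$feature_go]]
  if (a$sigma2_f > 0 && length(feat_snps) == 0)
    stopf("architecture GO term %s has no SNPs in the feature map", a$feature_go)
  with_seed(config$seed + 2L, {
    q <- length(panel$line_ids)
    reps <- config$replicates_per_line
    n <- q * reps
    Wall <- center_scale(panel)
    scale_to <- function(x, v) {
      if (v == 0) return(x * 0)
      sv <- stats::var(as.numeric(x))
      if (sv == 0) stopf("degenerate genomic component (zero variance)")
      x * sqrt(v / sv)
    }
    pick_causal <- function(candidates, n_causal, frac, what) {
      if (frac == 0) return(integer(0))
      if (!is.null(n_causal)) {
        if (n_causal < 1) stopf("zero causal SNPs requested for %s with nonzero variance", what)
        if (n_causal > length(candidates))
          stopf("n_causal for %s exceeds available SNPs", what)
        sort(sample(candidates, n_causal))
      } else candidates
    }
    causal_gene <- NA_character_
    cand_f <- feat_snps
    if (a$causal_gene && a$sigma2_f > 0) {
      genes <- fmap$go_to_genes[[a$feature_go]]
      sizes <- lengths(fmap$gene_to_snps[genes])
      causal_gene <- genes[which.max(sizes)]
      cand_f <- intersect(fmap$gene_to_snps[[causal_gene]], feat_snps)
    }
    cf <- pick_causal(cand_f, a$n_causal_f, a$sigma2_f, "feature component")
    cr <- pick_causal(setdiff(seq_len(ncol(panel$geno)), feat_snps),
                      a$n_causal_r, a$sigma2_r, "remainder component")
    sf <- if (length(cf)) stats::rnorm(length(cf)) else numeric(0)
    sr <- if (length(cr)) stats::rnorm(length(cr)) else numeric(0)
    g_f <- if (length(cf)) as.numeric(Wall$W[, cf, drop = FALSE] %*% sf) else rep(0, q)
    g_r <- if (length(cr)) as.numeric(Wall$W[, cr, drop = FALSE] %*% sr) else rep(0, q)
    if (a$sigma2_f > 0) { fac <- sqrt(a$sigma2_f / stats::var(g_f)); g_f <- g_f * fac; sf <- sf * fac }
    else g_f <- rep(0, q)
    if (a$sigma2_r > 0) { fac <- sqrt(a$sigma2_r / stats::var(g_r)); g_r <- g_r * fac; sr <- sr * fac }
    else g_r <- rep(0, q)
    g_tot <- g_f + g_r
    e <- stats::rnorm(n)
    e <- if (a$sigma2_e > 0) scale_to(e, a$sigma2_e) else rep(0, n)
    d_eff <- stats::rnorm(config$n_days, 0, config$fixed_effect_sd)
    b_eff <- stats::rnorm(config$n_blocks, 0, config$fixed_effect_sd)
    p_eff <- stats::rnorm(config$n_plates, 0, config$fixed_effect_sd)
    day <- sample(config$n_days, n, replace = TRUE)
    block <- sample(config$n_blocks, n, replace = TRUE)
    plate <- sample(config$n_plates, n, replace = TRUE)
    line_id <- rep(panel$line_ids, each = reps)
    li <- rep(seq_len(q), each = reps)
    value <- d_eff[day] + b_eff[block] + p_eff[plate] + g_tot[li] + e
    pheno <- data.frame(line_id = line_id,
                        replicate = rep(seq_len(reps), times = q),
                        day = sprintf("d%02d", day),
                        block = sprintf("b%02d", block),
                        plate = sprintf("p%02d", plate),
                        value = value)
    truth <- list(
      causal_f = panel$map$snp_id[cf], causal_r = panel$map$snp_id[cr],
      effects_f = stats::setNames(sf, panel$map$snp_id[cf]),
      effects_r = stats::setNames(sr, panel$map$snp_id[cr]),
      g_f = stats::setNames(g_f, panel$line_ids),
      g_r = stats::setNames(g_r, panel$line_ids),
      g_total = stats::setNames(g_tot, panel$line_ids),
      realized = c(var_f = stats::var(g_f), var_r = stats::var(g_r),
                   var_e = stats::var(e)),
      fixed_effects = list(day = d_eff, block = b_eff, plate = p_eff),
      causal_gene = causal_gene,
      feature_go = a$feature_go)
    list(pheno = pheno, truth = truth)
  })
}
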