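test_that("homozygous coding and minor-allele orientation hold for any config", {
  cfg <- sim_config(n_lines = 4, n_snps = 1, chrom_layout = c("1" = 1L),
                    maf_spectrum = list(dist = "fixed", value = 0.5),
                    n_genes = 1, n_go_terms = 1, replicates_per_line = 2,
                    seed = 3)
  panel <- simulate_genotype_panel(cfg)
  expect_true(all(panel$geno %in% c(0, 2)))
  for (seed in 1:5) {
    p <- simulate_genotype_panel(sim_config(n_lines = 30, n_snps = 100,
                                            n_genes = 10, n_go_terms = 2,
                                            seed = seed))
    expect_true(all(p$geno %in% c(0, 2)))
    expect_true(all(p$map$maf <= 0.5 & p$map$maf > 0))
    expect_equal(unname(colMeans(p$geno) / 2), p$map$maf)
    for (ch in unique(p$map$chrom))
      expect_true(all(diff(p$map$pos[p$map$chrom == ch]) > 0))
  }
})

test_that("seeded runs are bit-reproducible", {
  cfg <- sim_config(n_lines = 25, n_snps = 80, n_genes = 8, n_go_terms = 3,
                    replicates_per_line = 3, seed = 17)
  a <- simulate_genotype_panel(cfg)
  b <- simulate_genotype_panel(cfg)
  expect_identical(a, b)
  fa <- simulate_annotation(a, cfg)
  fb <- simulate_annotation(b, cfg)
  expect_identical(fa, fb)
  pa <- simulate_phenotypes(a, fa, cfg)
  pb <- simulate_phenotypes(b, fb, cfg)
  expect_identical(pa, pb)
})

test_that("mean empirical MAF matches a large-replicate simulation oracle", {
  # oracle: replicate the draw (uniform sampling frequency, binomial lines,
  # minor-orientation) directly, independent of the generator's code path
  n_lines <- 200
  set.seed(99)
  oracle <- replicate(30, {
    p <- runif(5000, 0.05, 0.5)
    f <- rbinom(5000, n_lines, p) / n_lines
    mean(pmin(f, 1 - f))
  })
  mu <- mean(oracle); se <- sd(oracle)
  panel <- simulate_genotype_panel(sim_config(n_lines = n_lines, n_snps = 5000,
                                              n_genes = 50, seed = 1))
  expect_lt(abs(mean(panel$map$maf) - mu), 3 * se + 3 * sd(panel$map$maf) / sqrt(5000))
})

test_that("invalid MAF spectra are rejected", {
  expect_error(sim_config(maf_spectrum = list(dist = "uniform", min = 0, max = 0.5)),
               "maf_spectrum")
  expect_error(sim_config(maf_spectrum = list(dist = "uniform", min = 0.1, max = 0.6)),
               "maf_spectrum")
  expect_error(sim_config(maf_spectrum = list(dist = "fixed", value = 0)),
               "maf_spectrum")
  expect_error(sim_config(architecture = list(sigma2_f = 0.5, sigma2_r = 0.1,
                                              sigma2_e = 0.1)),
               "sum to 1")
})

test_that("annotation tiles non-overlapping genes and leaves intergenic SNPs", {
  cfg <- sim_config(n_lines = 30, n_snps = 300, n_genes = 20, n_go_terms = 5,
                    seed = 8)
  panel <- simulate_genotype_panel(cfg)
  fmap <- simulate_annotation(panel, cfg)
  expect_length(fmap$gene_to_snps, 20)
  # non-overlap within chromosome
  for (ch in unique(fmap$genes$chrom)) {
    g <- fmap$genes[fmap$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  in_genes <- unique(unlist(fmap$gene_to_snps))
  expect_true(length(in_genes) < ncol(panel$geno))  # some SNPs intergenic
  expect_true(all(lengths(fmap$go_to_genes) >= 1))
  # every GO term's SNPs are the union of its genes' SNPs
  for (tm in names(fmap$go_to_snps))
    expect_identical(fmap$go_to_snps[[tm]],
                     sort(unique(unlist(fmap$gene_to_snps[fmap$go_to_genes[[tm]]]))))
  expect_error(simulate_annotation(panel, sim_config(n_lines = 30, n_snps = 300,
                                                     n_genes = 290, seed = 8)),
               "too large")
})

test_that("phenotypes carry the configured architecture exactly in-sample", {
  s <- quick_sim(5)
  expect_equal(nrow(s$pheno), 60 * 5)
  expect_equal(unname(s$truth$realized),
               c(0.3, 0.2, 0.5), tolerance = 1e-12)
  # per-line true genomic value equals genotype-weighted sum of causal effects
  W <- center_scale(s$panel)$W
  cf <- match(s$truth$causal_f, s$panel$map$snp_id)
  gf <- as.numeric(W[, cf] %*% s$truth$effects_f)
  expect_equal(gf, unname(s$truth$g_f), tolerance = 1e-10)
  # feature causal SNPs lie inside the designated GO term
  expect_true(all(cf %in% s$fmap$go_to_snps[[s$truth$feature_go]]))
})

test_that("null architectures and degenerate configs behave as stated", {
  s <- quick_sim(9, arch = list(feature_go = "GO:0001", sigma2_f = 0,
                                sigma2_r = 0, sigma2_e = 1))
  expect_true(all(s$truth$g_total == 0))
  lf <- fit_line_model(s$pheno)
  expect_lt(heritability_report(lf)$H2_individual, 0.1)
  cfg1 <- sim_config(n_lines = 40, n_snps = 100, n_genes = 10, n_go_terms = 2,
                     replicates_per_line = 1, seed = 2)
  panel <- simulate_genotype_panel(cfg1)
  fmap <- simulate_annotation(panel, cfg1)
  ph <- simulate_phenotypes(panel, fmap, cfg1)
  expect_equal(nrow(ph$pheno), 40)
  cfg_bad <- sim_config(n_lines = 40, n_snps = 100, n_genes = 10, n_go_terms = 2,
                        architecture = list(feature_go = "GO:0001",
                                            sigma2_f = 0.3, sigma2_r = 0.2,
                                            sigma2_e = 0.5, n_causal_f = 0),
                        seed = 2)
  expect_error(simulate_phenotypes(panel, fmap, cfg_bad), "zero causal")
})

test_that("realized total phenotypic variance approaches the configured unit", {
  vs <- vapply(1:10, function(seed) {
    s <- quick_sim(seed, n_lines = 80, n_snps = 200, reps = 8)
    # remove fixed effects (known truth) before measuring the unit variance
    fe <- s$truth$fixed_effects
    v <- s$pheno$value -
      fe$day[as.integer(sub("d", "", s$pheno$day))] -
      fe$block[as.integer(sub("b", "", s$pheno$block))] -
      fe$plate[as.integer(sub("p", "", s$pheno$plate))]
    var(v)
  }, 0)
  expect_lt(abs(mean(vs) - 1), 3 * sd(vs) / sqrt(length(vs)) + 0.02)
})

test_that("block-LD mode produces serially correlated, segregating SNPs", {
  cfg <- sim_config(n_lines = 60, n_snps = 200, n_genes = 10, n_go_terms = 2,
                    ld_blocks = list(block_size = 20, n_founders = 4,
                                     mutation = 0.01), seed = 13)
  panel <- simulate_genotype_panel(cfg)
  expect_true(all(panel$map$maf > 0))
  W <- center_scale(panel)$W
  adj <- abs(diag(cor(W[, 1:60])[-1, -60]))       # neighbours within blocks
  far <- abs(cor(W[, 1], W[, 101:160]))           # across chromosomes/blocks
  expect_gt(mean(adj), mean(far) + 0.2)
})
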