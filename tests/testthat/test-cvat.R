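scaled_toy <- function(n_lines, m, seed = 1) {
  set.seed(seed)
  repeat {
    g <- matrix(2 * rbinom(n_lines * m, 1, 0.4), n_lines, m)
    p <- colMeans(g) / 2
    if (all(p > 0 & p < 1)) break
  }
  center_scale(toy_panel(g))
}

test_that("back-solved SNP effects reproduce the least-squares projection", {
  # scalar case: s = w'g / w'w
  Wm1 <- scaled_toy(6, 1, seed = 3)
  g <- rnorm(6)
  s1 <- backsolve_snp_effects(Wm1, g)
  w <- Wm1$W[, 1]
  expect_equal(s1$effects, sum(w * g) / sum(w^2), tolerance = 1e-10)
  expect_equal(s1$fitted, as.numeric(w * s1$effects), tolerance = 1e-10)
  # zero input
  expect_true(all(backsolve_snp_effects(Wm1, rep(0, 6))$effects == 0))
  # 5-line 8-SNP toy vs normal-equations least squares (rank-deficient:
  # compare fitted values, which are unique)
  Wm2 <- scaled_toy(5, 8, seed = 7)
  set.seed(11); g2 <- rnorm(5)
  s2 <- backsolve_snp_effects(Wm2, g2)
  qrW <- qr(Wm2$W)
  fitted_ls <- qr.fitted(qrW, g2)
  expect_equal(s2$fitted, as.numeric(fitted_ls), tolerance = 1e-8)
  # W s reproduces g when g lies in the column space of W (as GFBLUP
  # genomic values do: G 1 = 0 forces them to sum to zero, and centered
  # W spans the zero-sum subspace once m is large enough)
  Wm3 <- scaled_toy(5, 20, seed = 9)
  set.seed(13); g3 <- rnorm(5); g3 <- g3 - mean(g3)
  s3 <- backsolve_snp_effects(Wm3, g3)
  expect_equal(s3$fitted, g3, tolerance = 1e-6)
})

test_that("gene-level genomic values are additive over disjoint covers", {
  Wm <- scaled_toy(8, 10, seed = 5)
  set.seed(2); g <- rnorm(8)
  s <- backsolve_snp_effects(Wm, g)
  fmap <- structure(list(
    gene_to_snps = list(gA = 1:4, gB = 5:10, gAll = 1:10, gNone = integer(0)),
    go_to_genes = list(t = c("gA", "gB"))), class = "feature_map")
  gA <- gene_genomic_values(Wm, s, fmap, "gA")
  gB <- gene_genomic_values(Wm, s, fmap, "gB")
  expect_lt(max(abs(gA + gB - s$fitted)), 1e-10)
  expect_equal(gene_genomic_values(Wm, s, fmap, "gAll"), s$fitted,
               tolerance = 1e-12)
  expect_equal(gene_genomic_values(Wm, s, fmap, "gNone"), rep(0, 8))
  # T additivity: disjoint exhaustive partition sums to ||proj g||^2
  expect_equal(cvat_statistic(g, gA) + cvat_statistic(g, gB),
               sum(g * s$fitted), tolerance = 1e-10)
})

test_that("the covariance statistic is a plain inner product", {
  expect_equal(cvat_statistic(c(1, -1, 2), c(0.5, 0.5, 1)), 2.0)
  expect_equal(cvat_statistic(c(1, 0), c(0, 5)), 0)
  g <- c(0.3, -1.2, 0.4)
  expect_equal(cvat_statistic(g, g), sum(g^2))
  expect_error(cvat_statistic(1:3, 1:4), "equal length")
})

test_that("circular permutation p-values match exhaustive enumeration", {
  m <- 6
  Wm <- scaled_toy(10, m, seed = 17)
  set.seed(21); g <- rnorm(10)
  fmap <- structure(list(
    gene_to_snps = list(g1 = 1:2, g2 = 3:6),
    go_to_genes = list(GOX = c("g1", "g2")),
    go_to_snps = list(GOX = 1:6)), class = "feature_map")
  res <- circular_permutation_test(Wm, g, fmap, "GOX", n_perm = 5, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, m - 1)
  # independent oracle: per-SNP covariance contributions computed one
  # inner product at a time, then every rotation enumerated by hand
  s <- backsolve_snp_effects(Wm, g)
  o <- vapply(1:m, function(j)
    cvat_statistic(g, Wm$W[, j] * s$effects[j]), 0)
  count <- c(g1 = 0, g2 = 0)
  T_obs <- c(g1 = cvat_statistic(g, Wm$W[, 1:2] %*% s$effects[1:2]),
             g2 = cvat_statistic(g, Wm$W[, 3:6] %*% s$effects[3:6]))
  expect_equal(sum(o[1:2]), unname(T_obs["g1"]), tolerance = 1e-10)
  for (k in 1:(m - 1)) {
    ok <- o[((seq_len(m) - 1 - k) %% m) + 1]
    Tk <- c(sum(ok[1:2]), sum(ok[3:6]))
    count <- count + (Tk >= T_obs)
  }
  p_oracle <- (1 + count) / (1 + (m - 1))
  tab <- res$table[order(res$table$gene_id), ]
  expect_equal(tab$p, unname(p_oracle[tab$gene_id]), tolerance = 1e-12)
  expect_equal(tab$T_obs, unname(T_obs[tab$gene_id]), tolerance = 1e-10)
})

test_that("a constant effect vector makes every gene's p equal 1", {
  # perfect LD: all GO SNP columns carry the same genotype vector, so the
  # minimum-norm back-solve spreads the signal evenly (s_i = 1/m) and every
  # rotation reproduces T_obs exactly
  set.seed(23)
  col <- 2 * rbinom(12, 1, 0.4)
  while (var(col) == 0) col <- 2 * rbinom(12, 1, 0.4)
  Wm <- center_scale(toy_panel(matrix(col, 12, 8)))
  g <- Wm$W[, 1]
  s <- backsolve_snp_effects(Wm, g)
  expect_lt(sd(s$effects), 1e-10)
  fmap <- structure(list(
    gene_to_snps = list(g1 = 1:3, g2 = 4:8),
    go_to_genes = list(GOX = c("g1", "g2")),
    go_to_snps = list(GOX = 1:8)), class = "feature_map")
  res <- circular_permutation_test(Wm, g, fmap, "GOX", n_perm = 7, seed = 1)
  expect_true(all(res$table$p == 1))
})

test_that("permutation p-values are invariant to relabeling of lines", {
  Wm <- scaled_toy(10, 12, seed = 29)
  set.seed(31); g <- rnorm(10)
  fmap <- structure(list(
    gene_to_snps = list(g1 = 1:5, g2 = 6:12),
    go_to_genes = list(GOX = c("g1", "g2")),
    go_to_snps = list(GOX = 1:12)), class = "feature_map")
  r1 <- circular_permutation_test(Wm, g, fmap, "GOX", n_perm = 11, seed = 2)
  perm <- sample(10)
  Wm2 <- Wm; Wm2$W <- Wm$W[perm, ]; Wm2$line_ids <- Wm$line_ids[perm]
  r2 <- circular_permutation_test(Wm2, g[perm], fmap, "GOX", n_perm = 11, seed = 2)
  expect_equal(r1$table$p, r2$table$p, tolerance = 1e-10)
})

test_that("gene ranking sorts by p, then descending statistic, then id", {
  base <- data.frame(go_id = "t", gene_id = c("gB", "gA", "gC"),
                     n_snps = c(3L, 2L, 4L),
                     T_obs = c(3.1, 2.0, 5.0),
                     p = c(0.05, 0.05, 0.20))
  base$minus_log10_p <- -log10(base$p)
  res <- structure(list(table = base, n_permutations = 99, exhaustive = FALSE,
                        seed = 1, go_id = "t"), class = "cvat_result")
  rk <- rank_genes(res)$table
  expect_equal(rk$gene_id, c("gB", "gA", "gC"))
  expect_equal(rk$rank, 1:3)
  # ties on both p and T fall back to gene id
  base2 <- base; base2$T_obs <- c(1, 1, 5); base2$p <- c(0.1, 0.1, 0.2)
  res2 <- structure(list(table = base2, n_permutations = 99, exhaustive = FALSE,
                         seed = 1, go_id = "t"), class = "cvat_result")
  expect_equal(rank_genes(res2)$table$gene_id, c("gA", "gB", "gC"))
  # singleton and degenerate guards
  expect_error(circular_permutation_test(scaled_toy(5, 1), rnorm(5),
                                         structure(list(gene_to_snps = list(),
                                                        go_to_genes = list()),
                                                   class = "feature_map"),
                                         "t"),
               "at least 2 SNPs")
})
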