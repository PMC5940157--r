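test_that("AI-REML matches brute-force numeric REML on small data", {
  # one-GRM toy: 5 lines, unbalanced replicates
  set.seed(101)
  ids <- paste0("L", 1:5)
  W <- matrix(rnorm(5 * 8), 5, 8)
  G <- tcrossprod(scale(W, scale = FALSE)) / 8
  dimnames(G) <- list(ids, ids)
  grm <- structure(list(G = G, m = 8, label = "total", line_ids = ids),
                   class = "grm")
  reps <- c(2, 3, 1, 2, 2)
  pheno <- data.frame(line_id = rep(ids, reps),
                      value = rnorm(sum(reps), rep(rnorm(5, 0, 1), reps), 0.7))
  fit <- fit_genomic_model(pheno, grm, tol = 1e-10)
  Z <- outer(pheno$line_id, ids, "==") * 1
  X <- matrix(1, nrow(pheno), 1)
  oracle <- dense_reml(pheno$value, X, list(Z %*% G %*% t(Z)))
  expect_equal(fit$logLik, oracle$logLR, tolerance = 1e-6)
  expect_equal(unname(fit$components), oracle$theta, tolerance = 1e-3)

  # two-GRM toy
  set.seed(202)
  W2 <- matrix(rnorm(5 * 6), 5, 6)
  G2 <- tcrossprod(scale(W2, scale = FALSE)) / 6
  dimnames(G2) <- list(ids, ids)
  grm2 <- structure(list(G = G2, m = 6, label = "feature", line_ids = ids),
                    class = "grm")
  grm$label <- "remainder"
  fit2 <- fit_genomic_model(pheno, list(grm2, grm), tol = 1e-10)
  oracle2 <- dense_reml(pheno$value, X,
                        list(Z %*% G2 %*% t(Z), Z %*% G %*% t(Z)))
  expect_equal(fit2$logLik, oracle2$logLR, tolerance = 1e-6)
})

test_that("line model REML log-likelihood matches direct numeric maximization", {
  # tiny 3-line, 2-replicate dataset; oracle maximizes the restricted
  # likelihood of the i.i.d. line model on a dense grid + optimizer
  set.seed(303)
  pheno <- data.frame(line_id = rep(c("a", "b", "c"), each = 2),
                      value = rnorm(6, rep(c(-1, 0, 1), each = 2), 0.5))
  ids <- c("a", "b", "c")
  fit <- fit_genomic_model(pheno, identity_grm(ids), tol = 1e-10)
  Z <- outer(pheno$line_id, ids, "==") * 1
  oracle <- dense_reml(pheno$value, matrix(1, 6, 1), list(Z %*% t(Z)))
  expect_equal(fit$logLik, oracle$logLR, tolerance = 1e-6)
})

test_that("GBLUP with identity kinship reproduces the lme4 line model", {
  s <- quick_sim(111, n_lines = 40, n_snps = 100, reps = 4)
  lf <- fit_line_model(s$pheno)
  gf <- fit_genomic_model(s$pheno, identity_grm(sort(unique(s$pheno$line_id))),
                          fixed = ~ day + block + plate, tol = 1e-10)
  expect_equal(unname(gf$components["sigma2_g"]),
               unname(lf$components["sigma2_L"]), tolerance = 1e-5)
  expect_equal(unname(gf$components["sigma2_e"]),
               unname(lf$components["sigma2_e"]), tolerance = 1e-5)
  expect_equal(unname(gf$ghat_total[lf$line_ids]),
               unname(lf$ghat_total), tolerance = 1e-4)
})

test_that("restricted likelihood trace is non-decreasing and BLUP algebra holds", {
  for (seed in c(7, 8)) {
    s <- quick_sim(seed, n_lines = 50, n_snps = 150, reps = 3)
    Wm <- center_scale(s$panel)
    part <- partition_grm(Wm, s$fmap$go_to_snps[["GO:0001"]])
    lf <- fit_line_model(s$pheno)
    yt <- adjust_phenotypes(lf)
    fit <- fit_genomic_model(yt, part)
    expect_true(all(diff(fit$trace) > -1e-8))
    # mixed-model residual identity: y - Xb = sum_k Z g_k + e
    resid <- fit$y - fit$Xb -
      fit$ghat_total[fit$records] - fit$ehat
    expect_lt(max(abs(resid)), 1e-8)
    expect_true(all(fit$components > 0))
  }
})

test_that("variance estimates recover simulation truth across seeds", {
  # moderate-scale recovery check (the full-scale one lives with the
  # acceptance suite): dense architecture, exact in-sample scaling
  ests <- t(vapply(1:6, function(seed) {
    s <- quick_sim(seed + 400, n_lines = 80, n_snps = 400, reps = 6)
    Wm <- center_scale(s$panel)
    part <- partition_grm(Wm, s$fmap$go_to_snps[["GO:0001"]])
    lf <- fit_line_model(s$pheno)
    yt <- adjust_phenotypes(lf)
    fit <- fit_genomic_model(yt, part)
    # map component scale to realized per-line variance via the centered GRM
    vfun <- function(G) {
      q <- nrow(G); Pc <- diag(q) - 1 / q
      sum(diag(Pc %*% G %*% Pc)) / (q - 1)
    }
    c(fit$components["sigma2_f"] * vfun(part$feature$G),
      fit$components["sigma2_r"] * vfun(part$remainder$G),
      fit$components["sigma2_e"])
  }, numeric(3)))
  mu <- colMeans(ests)
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  truth <- c(0.3, 0.2, 0.5)
  for (j in 1:3) expect_lt(abs(mu[j] - truth[j]), 3 * se[j] + 0.02)
})

test_that("heritability ratios follow the stated formulas", {
  # line-mean heritability from the printed individual-level fractions
  rep1 <- heritability_report(c(sigma2_g = 0.40, sigma2_e = 0.60), n_bar = 23)
  expect_equal(round(rep1$H2_line_means, 2), 0.94)
  expect_equal(rep1$H2_individual, 0.40, tolerance = 1e-12)
  # equal feature and remainder components split the genomic variance evenly
  rep2 <- heritability_report(c(sigma2_f = 0.2, sigma2_r = 0.2, sigma2_e = 0.6))
  expect_equal(rep2$h2_f, 0.5)
  expect_equal(rep2$h2_r, 0.5)
  expect_equal(rep2$h2_gfblup, 0.4, tolerance = 1e-12)
  # noiseless limit
  rep3 <- heritability_report(c(sigma2_g = 1, sigma2_e = 0))
  expect_equal(rep3$H2_individual, 1)
})

test_that("adjusted phenotypes equal y - Xb record for record", {
  s <- quick_sim(121, n_lines = 30, n_snps = 80, reps = 4)
  lf <- fit_line_model(s$pheno)
  yt <- adjust_phenotypes(lf)
  X <- model.matrix(~ factor(day) + factor(block) + factor(plate), s$pheno)
  # reconstruct Xb from the lme4 fixed effects
  beta <- lf$beta
  expect_lt(max(abs(yt$value - (s$pheno$value - lf$Xb))), 1e-8)
  # intercept-only balanced case reduces to centering
  ph0 <- data.frame(line_id = s$pheno$line_id, value = s$pheno$value)
  f0 <- fit_genomic_model(ph0, identity_grm(sort(unique(ph0$line_id))))
  yt0 <- adjust_phenotypes(f0)
  expect_equal(yt0$value, ph0$value - f0$mu, tolerance = 1e-10)
  # degenerate component: no genetic variance -> ytilde equals residuals
  set.seed(5)
  phn <- data.frame(line_id = rep(sprintf("L%02d", 1:25), each = 2),
                    value = rnorm(50))
  fn <- fit_genomic_model(phn, identity_grm(sprintf("L%02d", 1:25)))
  if (fn$components["sigma2_g"] < 1e-6) {
    ytn <- adjust_phenotypes(fn)
    expect_equal(ytn$value, fn$ehat + fn$ghat_total[fn$records],
                 tolerance = 1e-10)
  }
})

test_that("degenerate and singular designs are rejected informatively", {
  ph <- data.frame(line_id = rep(c("a", "b"), each = 3),
                   value = rnorm(6),
                   day = c("d1", "d1", "d1", "d2", "d2", "d2"),
                   dup = c("d1", "d1", "d1", "d2", "d2", "d2"))
  expect_error(fit_genomic_model(ph, identity_grm(c("a", "b")),
                                 fixed = ~ day + dup),
               "singular")
  expect_error(fit_line_model(data.frame(line_id = "a", value = 1)),
               "2 lines")
})
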