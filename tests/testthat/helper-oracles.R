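# Independent brute-force oracles used by the tests. These deliberately
# use dense n x n algebra and generic optimizers, not the package's
# reduced-dimension solver.

# Restricted log-likelihood (constant terms dropped, same convention as
# the package reports) computed densely from the full covariance.
dense_logLR <- function(theta, y, X, Vk_list) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Vk_list)) V <- V + theta[k] * Vk_list[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, TRUE)$modulus + determinant(XtViX, TRUE)$modulus +
            t(y) %*% P %*% y)[1]
}

# Numeric REML maximization over log-variances (multi-start Nelder-Mead).
dense_reml <- function(y, X, Vk_list, n_starts = 5) {
  K <- length(Vk_list)
  obj <- function(lt) -dense_logLR(exp(lt), y, X, Vk_list)
  best <- NULL
  vy <- var(y)
  set.seed(42)
  for (s in seq_len(n_starts)) {
    init <- log(rep(vy / (K + 1), K + 1)) + rnorm(K + 1, 0, if (s == 1) 0 else 1)
    o <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(theta = exp(best$par), logLR = -best$value)
}

# Dense mixed-model prediction of unobserved lines:
# ghat_v = C_vt V_t^{-1} (y_t - mu), all matrices built explicitly.
dense_predict <- function(sig, s2e, G_list, ref_ids, train_records, mu,
                          validation_lines) {
  ti <- unique(train_records$line_id)
  Zt <- outer(train_records$line_id, ti, "==") * 1
  q <- length(ti)
  Htt <- matrix(0, q, q)
  Hvt <- matrix(0, length(validation_lines), q)
  for (k in seq_along(G_list)) {
    Htt <- Htt + sig[k] * G_list[[k]][ti, ti, drop = FALSE]
    Hvt <- Hvt + sig[k] * G_list[[k]][validation_lines, ti, drop = FALSE]
  }
  Vt <- Zt %*% Htt %*% t(Zt) + diag(s2e, nrow(train_records))
  as.numeric(Hvt %*% t(Zt) %*% solve(Vt, train_records$value - mu))
}

# Small hand-built panel around explicit allele counts.
toy_panel <- function(geno, chrom = NULL, pos = NULL, qual = 1000) {
  m <- ncol(geno)
  genotype_panel(geno,
                 data.frame(snp_id = sprintf("s%02d", 1:m),
                            chrom = chrom %||% rep("1", m),
                            pos = pos %||% seq(100, by = 100, length.out = m),
                            qual = rep(qual, length.out = m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Identity-kinship grm over given line ids (for line-model equivalence).
identity_grm <- function(line_ids) {
  G <- diag(length(line_ids))
  dimnames(G) <- list(line_ids, line_ids)
  structure(list(G = G, m = length(line_ids), label = "total",
                 line_ids = line_ids), class = "grm")
}

# Small feature-enriched simulation shared by several tests.
quick_sim <- function(seed, n_lines = 60, n_snps = 400, reps = 5,
                      arch = list(feature_go = "GO:0001", sigma2_f = 0.3,
                                  sigma2_r = 0.2, sigma2_e = 0.5)) {
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps,
                    n_genes = max(3, n_snps %/% 16),
                    n_go_terms = 4, replicates_per_line = reps,
                    architecture = arch, seed = seed)
  panel <- simulate_genotype_panel(cfg)
  fmap <- simulate_annotation(panel, cfg)
  ph <- simulate_phenotypes(panel, fmap, cfg)
  list(cfg = cfg, panel = panel, fmap = fmap, pheno = ph$pheno,
       truth = ph$truth)
}
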