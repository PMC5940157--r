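#' Back-solve SNP effects for a GO term's genomic values
#'
#' Given the centered/scaled genotype matrix of a GO term's SNPs and the
#' per-line genomic feature values \eqn{\hat g_{GO}} (the feature
#' component of a converged GFBLUP fit), recovers per-SNP effects as
#' \eqn{\hat s = W_{GO}' (W_{GO} W_{GO}')^{+} \hat g_{GO}}, where the
#' pseudo-inverse drops eigenvalues below `1e-10` times the largest.
#' \eqn{W_{GO}\hat s} equals the projection of \eqn{\hat g_{GO}} onto the
#' column space of \eqn{W_{GO}}.
#'
#' @param W_GO `scaled_genotypes` restricted to the GO term's SNPs (genome
#'   order)
#' @param g_GO numeric vector of per-line genomic values, aligned to
#'   `W_GO$line_ids`
#' @return an object of class `snp_effects`: list with `effects` (per-SNP,
#'   genome order), `snp_index`, `fitted` (\eqn{W_{GO}\hat s}), `line_ids`
#' @export
backsolve_snp_effects <- function(W_GO, g_GO) {
  stopifnot(inherits(W_GO, "scaled_genotypes"))
  g_GO <- as.numeric(g_GO)
  if (length(g_GO) != nrow(W_GO$W))
    stopf("g_GO has length %d but W has %d lines", length(g_GO), nrow(W_GO$W))
  K <- tcrossprod(W_GO$W)
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values, 0)
  if (!any(keep)) {
    s <- rep(0, W_GO$m)
  } else {
    U <- eg$vectors[, keep, drop = FALSE]
    Kinv_g <- U %*% (crossprod(U, g_GO) / eg$values[keep])
    s <- as.numeric(crossprod(W_GO$W, Kinv_g))
  }
  structure(list(effects = s, snp_index = W_GO$snp_index,
                 fitted = as.numeric(W_GO$W %*% s), line_ids = W_GO$line_ids),
            class = "snp_effects")
}

#' Per-line genomic value of one gene within a GO term
#'
#' \eqn{\hat g_{gene} = \sum_{i \in gene} w_i \hat s_i}, summing the
#' gene's member SNP columns weighted by the back-solved effects. A gene
#' with no SNPs in the panel contributes a zero vector.
#'
#' @param W_GO `scaled_genotypes` of the GO term's SNPs
#' @param s an `snp_effects` object from [backsolve_snp_effects()]
#' @param fmap a `feature_map`
#' @param gene_id gene identifier (must belong to the GO term under study)
#' @return numeric per-line vector
#' @export
gene_genomic_values <- function(W_GO, s, fmap, gene_id) {
  stopifnot(inherits(W_GO, "scaled_genotypes"), inherits(s, "snp_effects"))
  gsnps <- fmap$gene_to_snps[[gene_id]]
  cols <- which(W_GO$snp_index %in% gsnps)
  if (length(cols) == 0) return(rep(0, nrow(W_GO$W)))
  as.numeric(W_GO$W[, cols, drop = FALSE] %*% s$effects[cols])
}

#' Covariance association test statistic
#'
#' \eqn{T_{CVAT} = \hat g_{GO} \cdot \hat g_{gene}}, the inner product
#' over lines between the GO term's genomic values and the gene's.
#'
#' @param g_GO,g_gene equal-length per-line numeric vectors
#' @return the scalar statistic
#' @export
cvat_statistic <- function(g_GO, g_gene) {
  if (length(g_GO) != length(g_gene)) stopf("vectors must have equal length")
  sum(g_GO * g_gene)
}

#' Gene-level CVAT with a circular-permutation null
#'
#' Partitions the genomic variance of a GO term among its member genes.
#' Observed statistics use the back-solved SNP effects in genome order;
#' The observed statistic decomposes exactly into per-SNP covariance
#' contributions, \eqn{T_{gene} = \sum_{i \in gene} o_i} with
#' \eqn{o_i = \hat s_i \, w_i'\hat g_{GO}}. The null rotates this
#' contribution vector cyclically along the term's genome-ordered SNPs by
#' a random offset in `1..m-1`: gene memberships and SNP positions stay
#' fixed while each position receives the (effect-aligned) contribution
#' of another SNP, so \eqn{T^*} is the gene's share of the term's genomic
#' variance under a random relocation along the genome — decoupling
#' effects from gene membership while preserving their serial
#' correlation. When `n_perm >= m - 1` all distinct rotations are
#' enumerated exhaustively instead of sampled.
#' One-tailed empirical p per gene:
#' \eqn{p = (1 + \#\{T^* \ge T_{obs}\}) / (1 + n_{perm})}, ties counting
#' against significance.
#'
#' @param W_GO `scaled_genotypes` of the GO term's SNPs, genome order
#' @param g_GO per-line genomic feature values of the term
#' @param fmap a `feature_map`; genes tested are the term's member genes
#' @param go_id the GO term identifier
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed for the random offsets
#' @return an object of class `cvat_result`: data.frame-backed list with
#'   `table` (gene_id, n_snps, T_obs, p, minus_log10_p, rank),
#'   `n_permutations` (effective count), `exhaustive`, `seed`, `go_id`
#' @export
circular_permutation_test <- function(W_GO, g_GO, fmap, go_id,
                                      n_perm = 10000, seed = 1) {
  stopifnot(inherits(W_GO, "scaled_genotypes"), inherits(fmap, "feature_map"))
  m <- W_GO$m
  if (m < 2) stopf("circular permutation needs at least 2 SNPs in the GO term")
  genes <- fmap$go_to_genes[[go_id]]
  if (is.null(genes) || length(genes) < 2)
    stopf("GO term %s needs at least 2 member genes", go_id)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  s <- backsolve_snp_effects(W_GO, g_GO)
  # exact decomposition of the statistic: T_gene = sum_{i in gene} o_i
  o <- s$effects * as.numeric(crossprod(W_GO$W, g_GO))
  cols <- lapply(genes, function(g) which(W_GO$snp_index %in% fmap$gene_to_snps[[g]]))
  T_obs <- vapply(cols, function(cc) sum(o[cc]), 0)
  exhaustive <- n_perm >= m - 1
  offsets <- if (exhaustive) seq_len(m - 1)
             else with_seed(seed, sample(m - 1, n_perm, replace = TRUE))
  n_eff <- length(offsets)
  ge_count <- numeric(length(genes))
  for (k in offsets) {
    # position j receives the contribution of position j - k (cyclically)
    ok <- o[((seq_len(m) - 1 - k) %% m) + 1]
    Tk <- vapply(cols, function(cc) sum(ok[cc]), 0)
    ge_count <- ge_count + (Tk >= T_obs - 1e-12 * pmax(abs(T_obs), 1))
  }
  p <- (1 + ge_count) / (1 + n_eff)
  tab <- data.frame(go_id = go_id, gene_id = genes,
                    n_snps = lengths(cols), T_obs = T_obs, p = p,
                    minus_log10_p = -log10(p))
  res <- structure(list(table = tab, n_permutations = n_eff,
                        exhaustive = exhaustive, seed = seed, go_id = go_id),
                   class = "cvat_result")
  rank_genes(res)
}

#' Rank genes of a CVAT result
#'
#' Sorts genes by ascending p-value, breaking ties by descending observed
#' statistic and then lexicographic gene id, and assigns ranks `1..n`.
#'
#' @param res a `cvat_result`
#' @return the `cvat_result` with `table` sorted and a `rank` column
#' @export
rank_genes <- function(res) {
  stopifnot(inherits(res, "cvat_result"))
  tab <- res$table
  if (nrow(tab) == 0) stopf("empty CVAT result")
  ord <- order(tab$p, -tab$T_obs, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  res$table <- tab
  res
}

#' @export
print.cvat_result <- function(x, ...) {
  cat(sprintf("cvat_result (%s): %d genes, %d permutations%s\n", x$go_id,
              nrow(x$table), x$n_permutations,
              if (x$exhaustive) " (exhaustive rotations)" else ""))
  print(utils::head(x$table, 10))
  invisible(x)
}
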