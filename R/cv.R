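#' Cross-validation scheme for predictive ability
#'
#' @param validation_fraction fraction of lines masked per repeat
#'   (default 0.10)
#' @param n_repeats number of random subdivisions (default 50)
#' @param seed integer seed; the seed fully determines the line splits, so
#'   two models evaluated under the same scheme see identical (paired)
#'   splits
#' @return an object of class `cv_scheme`
#' @export
cv_scheme <- function(validation_fraction = 0.10, n_repeats = 50, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must be in (0, 1)")
  if (n_repeats < 2) stopf("n_repeats must be >= 2")
  structure(list(validation_fraction = validation_fraction,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "cv_scheme")
}

cv_splits <- function(line_ids, scheme) {
  n_val <- ceiling(scheme$validation_fraction * length(line_ids))
  with_seed(scheme$seed, lapply(seq_len(scheme$n_repeats), function(i)
    sample(line_ids, n_val)))
}

#' Repeated hold-out cross-validation of predictive ability
#'
#' Per repeat, a random `validation_fraction` of the lines is masked,
#' variance components are re-estimated on the training records
#' (intercept-only model on adjusted phenotypes), held-out genomic values
#' are predicted with [predict_validation()], and the predictive ability
#' (PA) is the Pearson correlation between the validation lines' mean
#' adjusted phenotype and their predicted genomic value. Splits are fully
#' determined by the scheme seed, so different models evaluated under the
#' same scheme are compared on paired splits.
#'
#' @param ytilde data.frame of adjusted phenotype records (`line_id`,
#'   `value`)
#' @param grms a `grm` or list of 1-2 `grm` objects (GBLUP or GFBLUP)
#' @param scheme a [cv_scheme()]
#' @param label model label carried into the result (default from the GRM
#'   set: "GBLUP" or "GFBLUP")
#' @return an object of class `cv_result`: list with `pa` (per-repeat
#'   predictive ability), `mean_pa`, `se` (sd(pa)/sqrt(n_repeats)),
#'   `model`, `splits` (validation line sets), `scheme`
#' @export
cross_validate <- function(ytilde, grms, scheme = cv_scheme(), label = NULL) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(inherits(scheme, "cv_scheme"))
  ytilde <- as.data.frame(ytilde)
  line_ids <- grms[[1]]$line_ids
  line_ids <- line_ids[line_ids %in% ytilde$line_id]
  if (length(line_ids) < 20) stopf("cross-validation needs at least 20 lines")
  label <- label %||% if (length(grms) == 1) "GBLUP" else "GFBLUP"
  splits <- cv_splits(line_ids, scheme)
  pa <- rep(NA_real_, scheme$n_repeats)
  for (i in seq_len(scheme$n_repeats)) {
    val <- splits[[i]]
    if (length(val) < 3) {
      warning(sprintf("repeat %d skipped: validation set has < 3 lines", i),
              call. = FALSE)
      next
    }
    train <- ytilde[!(ytilde$line_id %in% val), , drop = FALSE]
    fit <- fit_genomic_model(train, grms)
    gv <- predict_validation(fit, grms, train, val)
    obs <- tapply(ytilde$value[ytilde$line_id %in% val],
                  ytilde$line_id[ytilde$line_id %in% val], mean)[val]
    pa[i] <- if (stats::sd(gv) < .Machine$double.eps^0.5) 0
             else stats::cor(as.numeric(obs), as.numeric(gv))
  }
  ok <- !is.na(pa)
  structure(list(pa = pa[ok], mean_pa = mean(pa[ok]),
                 se = stats::sd(pa[ok]) / sqrt(sum(ok)),
                 model = label, splits = splits, scheme = scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): mean PA = %.3f +/- %.3f over %d repeats\n",
              x$model, x$mean_pa, x$se, length(x$pa)))
  invisible(x)
}

#' One-sided Welch test for increased predictive ability
#'
#' Tests H1: mean PA(feature model) > mean PA(null model) with Welch's
#' unequal-variance t-test (Welch-Satterthwaite degrees of freedom).
#' If both PA vectors are degenerate (zero variance), the documented
#' convention is p = 0 when the feature mean exceeds the null mean and
#' p = 1 otherwise.
#'
#' @param feature_cv,null_cv `cv_result` objects (or numeric PA vectors)
#' @return the one-sided p-value
#' @export
compare_models <- function(feature_cv, null_cv) {
  x <- if (inherits(feature_cv, "cv_result")) feature_cv$pa else feature_cv
  y <- if (inherits(null_cv, "cv_result")) null_cv$pa else null_cv
  if (length(x) == 0 || length(y) == 0) stopf("empty PA vector")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) > mean(y)) 0 else 1)
  stats::t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`
#' @return adjusted p-values, same order
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Percent of line-mean heritability accounted for by a prediction model
#'
#' The maximum predictive ability of line means satisfies
#' \eqn{H^2 = r^2 = PA^2}, so a model with mean predictive ability `PA`
#' accounts for \eqn{PA^2 / H^2_{\bar y}} of the line-mean heritability.
#'
#' @param mean_PA mean predictive ability in `[0, 1]`
#' @param H2_line_means line-mean heritability in `[0, 1]`
#' @return the percentage `100 * PA^2 / H2_line_means`
#' @export
summarize_percent_heritability <- function(mean_PA, H2_line_means) {
  if (mean_PA < 0 || mean_PA > 1 || H2_line_means < 0 || H2_line_means > 1)
    stopf("inputs must lie in [0, 1]")
  100 * mean_PA^2 / H2_line_means
}

#' Scan GO terms for increased predictive ability (GFBLUP vs GBLUP)
#'
#' For every GO term in the feature map with at least `min_snps` member
#' SNPs (and a nonempty remainder), the total GRM is partitioned, the
#' GFBLUP model is cross-validated on the same line splits as the GBLUP
#' null, and the one-sided Welch p-value for increased predictive ability
#' is computed; p-values are FDR-adjusted across terms. The reported
#' `h2_f` comes from a single GFBLUP fit on all data.
#'
#' @param ytilde adjusted phenotype records (`line_id`, `value`)
#' @param Wm `scaled_genotypes` for the full filtered panel
#' @param fmap a `feature_map` with GO level populated
#' @param scheme a [cv_scheme()] shared by all models
#' @param min_snps minimum member SNPs for a term to be scanned (default 2)
#' @return list with `table` (data.frame: go_id, n_genes, n_snps, mean_PA,
#'   SE, p, FDR_p, h2_f, one row per scanned term, sorted by decreasing
#'   mean_PA), `null_cv` (the GBLUP `cv_result`), `cv` (per-term
#'   `cv_result`s)
#' @export
scan_go_terms <- function(ytilde, Wm, fmap, scheme = cv_scheme(), min_snps = 2) {
  stopifnot(inherits(Wm, "scaled_genotypes"), inherits(fmap, "feature_map"))
  if (length(fmap$go_to_snps) == 0) stopf("feature map has no GO terms with SNPs")
  G <- compute_grm(Wm, "total")
  null_cv <- cross_validate(ytilde, G, scheme, label = "GBLUP")
  terms <- names(fmap$go_to_snps)
  rows <- list(); cvs <- list()
  for (tm in terms) {
    snps <- intersect(fmap$go_to_snps[[tm]], Wm$snp_index)
    if (length(snps) < min_snps || length(snps) >= Wm$m) {
      msgf("scan_go_terms: skipping %s (%d usable SNPs)", tm, length(snps))
      next
    }
    part <- partition_grm(Wm, snps)
    fcv <- cross_validate(ytilde, part, scheme, label = paste0("GFBLUP:", tm))
    full <- fit_genomic_model(ytilde, part)
    h2f <- heritability_report(full)$h2_f
    rows[[tm]] <- data.frame(
      go_id = tm, n_genes = length(fmap$go_to_genes[[tm]]),
      n_snps = length(snps), mean_PA = fcv$mean_pa, SE = fcv$se,
      p = compare_models(fcv, null_cv), h2_f = h2f)
    cvs[[tm]] <- fcv
  }
  if (length(rows) == 0) stopf("no GO term passed the scan preconditions")
  tab <- do.call(rbind, rows)
  tab$FDR_p <- fdr_adjust(tab$p)
  tab <- tab[order(-tab$mean_PA), c("go_id", "n_genes", "n_snps", "mean_PA",
                                    "SE", "p", "FDR_p", "h2_f")]
  rownames(tab) <- NULL
  list(table = tab, null_cv = null_cv, cv = cvs)
}
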