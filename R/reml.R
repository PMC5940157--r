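#' @name variance_models
#' @title REML variance-component models for replicated inbred-line records
#'
#' @description
#' Two model families share the record-level representation
#' \eqn{y = X b + Z g + e}, with `Z` the incidence of records onto lines:
#' the line model (i.i.d. line effects, broad-sense heritability) and the
#' genomic models, where line effects have covariance proportional to one
#' (GBLUP) or two (GFBLUP feature + remainder) genomic relationship
#' matrices. Genomic models are estimated by average-information REML
#' (AI-REML) with step-halving and an EM-type fallback; the line model is
#' delegated to \pkg{lme4}.
NULL

# ---- internal AI-REML machinery -------------------------------------------
#
# V = sum_k sigma2_k Z G_k Z' + sigma2_e I with a single line incidence Z.
# All linear algebra is reduced to the q x q line level through the
# push-through identity
#   (sigma2_e I_n + Z H Z')^{-1} = (I - Z H S^{-1} Z') / sigma2_e,
#   S = sigma2_e I_q + (Z'Z) H,   H = sum_k sigma2_k G_k,
# which does not require H to be invertible (feature GRMs are often
# rank-deficient). log|V| = (n - q) log sigma2_e + log|S|.

reml_state <- function(theta, Gs, li, nvec, y, X) {
  K <- length(Gs); q <- length(nvec); n <- length(y)
  s2e <- theta[K + 1]
  H <- matrix(0, q, q)
  for (k in seq_len(K)) H <- H + theta[k] * Gs[[k]]
  S <- sweep(H, 1, nvec, "*")
  diag(S) <- diag(S) + s2e
  Sinv <- solve(S)
  B <- H %*% Sinv                       # symmetric: H (s2e I + N H)^{-1}
  vmult <- function(M) {
    M <- as.matrix(M)
    Zt <- rowsum(M, li)  # relies on li being 1..q-coded
    (M - (B %*% Zt)[li, , drop = FALSE]) / s2e
  }
  ld <- determinant(S, logarithm = TRUE)
  logdetV <- (n - q) * log(s2e) + as.numeric(ld$modulus)
  VinvX <- vmult(X)
  Vinvy <- vmult(y)
  XtVX <- crossprod(X, VinvX)
  bhat <- solve(XtVX, crossprod(X, Vinvy))
  Py <- Vinvy - VinvX %*% bhat
  yPy <- sum(y * Py)
  logLR <- -0.5 * (logdetV + as.numeric(determinant(XtVX, TRUE)$modulus) + yPy)
  list(theta = theta, H = H, B = B, vmult = vmult, VinvX = VinvX,
       XtVX = XtVX, bhat = bhat, Py = Py, logLR = logLR, s2e = s2e)
}

reml_derivs <- function(st, Gs, li, nvec, X) {
  K <- length(Gs); n <- length(st$Py); q <- length(nvec)
  s2e <- st$s2e
  u <- rowsum(st$Py, li)            # q x 1, Z'Py
  ZtVinvX <- rowsum(st$VinvX, li)   # q x p
  NB <- sweep(st$B, 1, nvec, "*")
  T0 <- (diag(nvec) - sweep(NB, 2, nvec, "*")) / s2e # Z'V^{-1}Z
  grad <- numeric(K + 1)
  yPVP <- numeric(K + 1)
  trPV <- numeric(K + 1)
  fs <- vector("list", K + 1)
  for (k in seq_len(K)) {
    Gu <- Gs[[k]] %*% u
    yPVP[k] <- sum(u * Gu)
    tr1 <- sum(T0 * Gs[[k]])
    M <- crossprod(ZtVinvX, Gs[[k]] %*% ZtVinvX)
    tr2 <- sum(diag(solve(st$XtVX, M)))
    trPV[k] <- tr1 - tr2
    fs[[k]] <- Gu[li, , drop = FALSE]                # Z G_k Z' P y
  }
  yPVP[K + 1] <- sum(st$Py^2)
  trVinv <- (n - sum(diag(st$B) * nvec)) / s2e
  trPV[K + 1] <- trVinv - sum(diag(solve(st$XtVX, crossprod(st$VinvX))))
  fs[[K + 1]] <- st$Py
  grad <- -0.5 * (trPV - yPVP)
  pmultf <- function(f) {
    vf <- st$vmult(f)
    vf - st$VinvX %*% solve(st$XtVX, crossprod(X, vf))
  }
  Pf <- lapply(fs, pmultf)
  AI <- matrix(0, K + 1, K + 1)
  for (k in seq_len(K + 1)) for (l in k:(K + 1)) {
    AI[k, l] <- 0.5 * sum(fs[[k]] * Pf[[l]])
    AI[l, k] <- AI[k, l]
  }
  list(grad = grad, AI = AI, yPVP = yPVP, trPV = trPV)
}

aireml <- function(y, X, Gs, li, q, maxit = 200, tol = 1e-6, verbose = FALSE) {
  n <- length(y)
  nvec <- tabulate(li, q)
  vary <- stats::var(y)
  if (!is.finite(vary) || vary <= 0) stopf("phenotype variance is zero; nothing to fit")
  lb <- 1e-8 * vary
  K <- length(Gs)
  theta <- rep(vary / (K + 1), K + 1)
  st <- reml_state(theta, Gs, li, nvec, y, X)
  converged <- FALSE
  trace <- numeric(0)
  it <- 0
  while (it < maxit) {
    it <- it + 1
    dv <- reml_derivs(st, Gs, li, nvec, X)
    step <- tryCatch(solve(dv$AI, dv$grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      fac <- 1
      for (h in 0:10) {
        cand <- pmax(theta + fac * step, lb)
        stc <- tryCatch(reml_state(cand, Gs, li, nvec, y, X),
                        error = function(e) NULL)
        if (!is.null(stc) && is.finite(stc$logLR) && stc$logLR >= st$logLR - 1e-12) {
          accepted <- TRUE; break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {
      # EM-type multiplicative fixed point: positivity-preserving ascent
      cand <- pmax(theta * dv$yPVP / pmax(dv$trPV, .Machine$double.eps), lb)
      stc <- tryCatch(reml_state(cand, Gs, li, nvec, y, X), error = function(e) NULL)
      if (is.null(stc) || !is.finite(stc$logLR)) break
    }
    dll <- stc$logLR - st$logLR
    rel <- max(abs(cand - theta) / pmax(theta, 1e-6 * vary))
    theta <- cand; st <- stc
    trace <- c(trace, st$logLR)
    if (verbose) msgf("  iter %d logLR %.6f", it, st$logLR)
    if (abs(dll) < tol && rel < tol) { converged <- TRUE; break }
  }
  u <- rowsum(st$Py, li)
  ghat <- matrix(0, q, K)
  for (k in seq_len(K)) ghat[, k] <- theta[k] * (Gs[[k]] %*% u)
  ehat <- as.numeric(theta[K + 1] * st$Py)
  list(theta = theta, bhat = as.numeric(st$bhat), ghat = ghat, ehat = ehat,
       logLik = st$logLR, iterations = it, converged = converged,
       trace = trace, lower_bound = lb)
}

# ---- public fitting interface ---------------------------------------------

#' Fit a GBLUP or GFBLUP model by AI-REML
#'
#' Fits \eqn{y = X b + Z g + e} where the line effects `g` decompose over
#' one GRM (GBLUP, Model "total") or a feature/remainder pair (GFBLUP).
#' Variance components are estimated by average-information REML: each
#' component starts at var(y)/(number of components); an AI step that
#' decreases the restricted likelihood is halved up to 10 times before an
#' EM-type update is taken instead; components proposed below the bound
#' `1e-8 * var(y)` are clamped there; convergence requires both the change
#' in restricted log-likelihood and the maximum relative parameter change
#' to drop below `tol`.
#'
#' @param pheno data.frame with columns `line_id`, `value`, plus any
#'   covariates named in `fixed`. For fixed-effect-adjusted phenotypes use
#'   the default intercept-only `fixed = ~ 1`.
#' @param grms a single `grm` or a list of 1-2 `grm` objects (labels
#'   `total`, or `feature` + `remainder`) sharing identical line ids.
#' @param fixed one-sided formula for the fixed effects (reference-level
#'   indicator coding with explicit intercept); default `~ 1`.
#' @param maxit,tol AI-REML iteration cap (default 200) and convergence
#'   tolerance (default 1e-6).
#' @param verbose print the iteration trace.
#' @return an object of class `variance_estimate` with elements
#'   `components` (named: `sigma2_g` or `sigma2_f`/`sigma2_r`, plus
#'   `sigma2_e`), `beta` (fixed effects incl. intercept `mu`), `mu`,
#'   `ghat` (line x component matrix plus total attribute), `ghat_total`,
#'   `ehat` (per record), `logLik` (restricted), `iterations`, `converged`,
#'   `line_ids`, `records` (line_id per record), `Xb` (fitted fixed part),
#'   `y`.
#' @export
fit_genomic_model <- function(pheno, grms, fixed = ~ 1, maxit = 200,
                              tol = 1e-6, verbose = FALSE) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, length(grms) <= 2,
            all(vapply(grms, inherits, TRUE, "grm")))
  labels <- vapply(grms, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("GRMs must have distinct labels")
  pheno <- as.data.frame(pheno)
  if (!all(c("line_id", "value") %in% names(pheno)))
    stopf("pheno must contain columns line_id and value")
  pheno$line_id <- as.character(pheno$line_id)
  ref_ids <- grms[[1]]$line_ids
  for (g in grms) if (!identical(g$line_ids, ref_ids))
    stopf("all GRMs must share identical line ids in identical order")
  if (!all(pheno$line_id %in% ref_ids))
    stopf("phenotype lines absent from GRM: %s",
          paste(utils::head(setdiff(pheno$line_id, ref_ids), 5), collapse = ", "))
  lines_fit <- ref_ids[ref_ids %in% pheno$line_id]
  sel <- match(lines_fit, ref_ids)
  Gs <- lapply(grms, function(g) {
    Gi <- g$G[sel, sel, drop = FALSE]
    ev <- min(eigen(Gi, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(diag(Gi)))))
      stopf("GRM '%s' is not positive semidefinite (min eigenvalue %.3g)", g$label, ev)
    Gi
  })
  li <- match(pheno$line_id, lines_fit)
  X <- stats::model.matrix(fixed, pheno)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("fixed design is singular; aliased columns: %s",
          paste(colnames(X)[-seq_len(qrX$rank)][seq_len(ncol(X) - qrX$rank)]
                %||% "?", collapse = ", "))
  fit <- aireml(pheno$value, X, Gs, li, length(lines_fit),
                maxit = maxit, tol = tol, verbose = verbose)
  if (!fit$converged)
    warning("AI-REML did not converge within maxit; estimates are flagged",
            call. = FALSE)
  comp_names <- c(total = "sigma2_g", feature = "sigma2_f",
                  remainder = "sigma2_r")[labels]
  components <- stats::setNames(fit$theta, c(comp_names, "sigma2_e"))
  ghat <- fit$ghat
  dimnames(ghat) <- list(lines_fit, comp_names)
  beta <- stats::setNames(fit$bhat, colnames(X))
  if ("(Intercept)" %in% names(beta)) names(beta)[names(beta) == "(Intercept)"] <- "mu"
  structure(list(components = components, beta = beta,
                 mu = unname(beta["mu"]),
                 ghat = ghat, ghat_total = rowSums(ghat),
                 ehat = fit$ehat, logLik = fit$logLik,
                 iterations = fit$iterations, converged = fit$converged,
                 trace = fit$trace, line_ids = lines_fit,
                 records = pheno$line_id,
                 Xb = as.numeric(X %*% fit$bhat), y = pheno$value,
                 model = if (length(Gs) == 1) "GBLUP" else "GFBLUP"),
            class = "variance_estimate")
}

#' Fit the line model for broad-sense heritability
#'
#' The mixed model `value ~ day + block + plate + (1 | line_id)` with
#' i.i.d. line effects, fitted by REML via [lme4::lmer()] (fixed factors
#' with fewer than two observed levels are dropped from the formula).
#' Broad-sense heritability at the individual level is
#' \eqn{H^2 = \sigma^2_L / (\sigma^2_L + \sigma^2_E)}.
#'
#' @param pheno data.frame with columns `line_id`, `value`, and optionally
#'   `day`, `block`, `plate` (treated as factors).
#' @return a `variance_estimate` with components `sigma2_L`, `sigma2_e`.
#' @export
fit_line_model <- function(pheno) {
  pheno <- as.data.frame(pheno)
  if (!all(c("line_id", "value") %in% names(pheno)))
    stopf("pheno must contain columns line_id and value")
  pheno$line_id <- as.character(pheno$line_id)
  if (length(unique(pheno$line_id)) < 2) stopf("need at least 2 lines")
  terms <- character(0)
  for (f in c("day", "block", "plate")) {
    if (f %in% names(pheno)) {
      pheno[[f]] <- factor(pheno[[f]])
      if (nlevels(pheno[[f]]) >= 2) terms <- c(terms, f)
    }
  }
  rhs <- paste(c(if (length(terms)) terms else "1", "(1 | line_id)"),
               collapse = " + ")
  if (length(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms), pheno)
    if (qr(X)$rank < ncol(X))
      stopf("fixed design is singular after reference-level coding (aliased day/block/plate levels)")
  }
  fm <- lme4::lmer(stats::as.formula(paste("value ~", rhs)), data = pheno,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fm))
  s2L <- vc$vcov[vc$grp == "line_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  re <- lme4::ranef(fm)$line_id
  ghat <- stats::setNames(re[["(Intercept)"]], rownames(re))
  line_ids <- sort(unique(pheno$line_id))
  ghat <- ghat[line_ids]
  beta <- lme4::fixef(fm)
  names(beta)[names(beta) == "(Intercept)"] <- "mu"
  Xb <- as.numeric(stats::fitted(fm)) -
    ghat[pheno$line_id]                       # fitted = Xb + Z ghat
  ehat <- pheno$value - as.numeric(stats::fitted(fm))
  nbar <- mean(table(pheno$line_id))
  structure(list(components = c(sigma2_L = s2L, sigma2_e = s2e),
                 beta = beta, mu = unname(beta["mu"]),
                 ghat = cbind(line = ghat), ghat_total = ghat,
                 ehat = ehat, logLik = as.numeric(stats::logLik(fm)),
                 iterations = NA_integer_, converged = TRUE,
                 line_ids = line_ids, records = pheno$line_id,
                 Xb = Xb, y = pheno$value, n_bar = nbar,
                 model = "line"),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("variance_estimate (%s): %s\n", x$model,
              paste(sprintf("%s = %.4g", names(x$components), x$components),
                    collapse = ", ")))
  cat(sprintf("  logLik(REML) = %.4f, converged = %s\n", x$logLik, x$converged))
  invisible(x)
}

#' Heritability ratios from fitted variance components
#'
#' Computes, from whichever components are present:
#' individual-level broad/genomic heritability
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} (with
#' \eqn{\sigma^2_g} the total among-line variance, i.e. \eqn{\sigma^2_L},
#' \eqn{\sigma^2_g}, or \eqn{\sigma^2_f + \sigma^2_r});
#' line-mean heritability
#' \eqn{H^2_{\bar y} = \sigma^2_g / (\sigma^2_g + \sigma^2_e / \bar n)}
#' for `n_bar` replicates per line; and for two-component fits the genomic
#' split \eqn{h^2_f = \sigma^2_f / (\sigma^2_f + \sigma^2_r)},
#' \eqn{h^2_r = 1 - h^2_f}.
#'
#' @param est a `variance_estimate`, or a named numeric vector of variance
#'   components (names among `sigma2_L`, `sigma2_g`, `sigma2_f`,
#'   `sigma2_r`, `sigma2_e`).
#' @param n_bar mean number of replicate records per line (for the
#'   line-mean ratio); defaults to the estimate's own `n_bar` if recorded.
#' @return an object of class `heritability_report`: list with
#'   `H2_individual`, `H2_line_means`, `h2_gblup`, `h2_gfblup`, `h2_f`,
#'   `h2_r`, `n_bar` (fields not defined for the fit are `NA`).
#' @export
heritability_report <- function(est, n_bar = NULL) {
  if (inherits(est, "variance_estimate")) {
    if (!isTRUE(est$converged))
      warning("using a non-converged variance estimate", call. = FALSE)
    comp <- est$components
    n_bar <- n_bar %||% est$n_bar
  } else comp <- est
  gv <- function(nm) if (nm %in% names(comp)) unname(comp[nm]) else NA_real_
  se <- gv("sigma2_e")
  sf <- gv("sigma2_f"); sr <- gv("sigma2_r")
  sg <- if (!is.na(gv("sigma2_g"))) gv("sigma2_g")
        else if (!is.na(gv("sigma2_L"))) gv("sigma2_L")
        else sf + sr
  H2_ind <- sg / (sg + se)
  H2_lm <- if (!is.null(n_bar)) sg / (sg + se / n_bar) else NA_real_
  h2_f <- if (!is.na(sf)) sf / (sf + sr) else NA_real_
  structure(list(
    H2_individual = H2_ind,
    H2_line_means = H2_lm,
    h2_gblup = if (!is.na(gv("sigma2_g"))) gv("sigma2_g") / (gv("sigma2_g") + se) else NA_real_,
    h2_gfblup = if (!is.na(sf)) (sf + sr) / (sf + sr + se) else NA_real_,
    h2_f = h2_f, h2_r = if (!is.na(h2_f)) 1 - h2_f else NA_real_,
    n_bar = n_bar %||% NA_real_), class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, ...) {
  for (nm in names(x)) if (!is.na(x[[nm]]))
    cat(sprintf("  %-14s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Adjust phenotypes for fixed effects
#'
#' Returns the record-level adjusted phenotype
#' \eqn{\tilde y_{ij} = \hat g_i + \hat e_{ij}}, which equals
#' \eqn{y - X\hat b} (intercept included) record for record by the BLUP
#' decomposition of the fitted model.
#'
#' @param est a `variance_estimate` fitted on `pheno`
#' @param pheno the phenotype table the model was fitted on (same record
#'   order); defaults to the records stored in the fit
#' @return data.frame with columns `line_id`, `value` (the adjusted
#'   phenotype), one row per input record
#' @export
adjust_phenotypes <- function(est, pheno = NULL) {
  stopifnot(inherits(est, "variance_estimate"))
  line_id <- est$records
  ytilde <- est$ghat_total[line_id] + est$ehat
  chk <- est$y - est$Xb
  if (max(abs(ytilde - chk)) > 1e-8)
    warning("BLUP decomposition mismatch beyond 1e-8; check the fit", call. = FALSE)
  data.frame(line_id = line_id, value = as.numeric(ytilde))
}
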