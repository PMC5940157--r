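#' Predict genomic values of validation lines from a training fit
#'
#' Computes the held-out genomic values with the cross-block rows of the
#' GRM(s): for a single component
#' \eqn{\hat g_v = \hat\sigma^2_g G_{v,t} Z_t' V_t^{-1} (\tilde y_t - \hat\mu_t)}
#' with \eqn{V_t = Z_t G_{t,t} Z_t' \hat\sigma^2_g + I \hat\sigma^2_e},
#' and for a feature/remainder pair the analogue with
#' \eqn{G_{f,v,t}\hat\sigma^2_f + G_{r,v,t}\hat\sigma^2_r} in place of the
#' single cross-block. Repeated training records are handled through the
#' training incidence \eqn{Z_t}; \eqn{\hat\mu_t} is the GLS intercept of
#' the training fit.
#'
#' @param train_fit a `variance_estimate` from [fit_genomic_model()] fitted
#'   on the training records only (intercept-only fixed part)
#' @param grms the full-panel `grm` list (1 or 2, matching the fit) whose
#'   line ids cover both training and validation lines
#' @param ytilde_train data.frame of the training records (`line_id`,
#'   `value`) the model was fitted on
#' @param validation_lines character vector of held-out line ids (absent
#'   from the training records)
#' @return named numeric vector of predicted genomic values, one per
#'   validation line
#' @export
predict_validation <- function(train_fit, grms, ytilde_train, validation_lines) {
  stopifnot(inherits(train_fit, "variance_estimate"))
  if (inherits(grms, "grm")) grms <- list(grms)
  validation_lines <- as.character(validation_lines)
  ref_ids <- grms[[1]]$line_ids
  if (!all(validation_lines %in% ref_ids)) stopf("validation lines absent from GRM")
  if (any(validation_lines %in% ytilde_train$line_id))
    stopf("validation lines present in training records")
  comp <- train_fit$components
  s2e <- unname(comp["sigma2_e"])
  sig <- unname(comp[setdiff(names(comp), "sigma2_e")])
  labels <- vapply(grms, `[[`, "", "label")
  train_lines <- train_fit$line_ids
  ti <- match(train_lines, ref_ids)
  vi <- match(validation_lines, ref_ids)
  li <- match(ytilde_train$line_id, train_lines)
  n <- nrow(ytilde_train)
  q <- length(train_lines)
  nvec <- tabulate(li, q)
  # line-level blended covariances
  Htt <- matrix(0, q, q)
  Hvt <- matrix(0, length(vi), q)
  for (k in seq_along(grms)) {
    Htt <- Htt + sig[k] * grms[[k]]$G[ti, ti, drop = FALSE]
    Hvt <- Hvt + sig[k] * grms[[k]]$G[vi, ti, drop = FALSE]
  }
  # V_t^{-1} r via the q-level push-through identity
  r <- ytilde_train$value - train_fit$mu
  S <- sweep(Htt, 1, nvec, "*")
  diag(S) <- diag(S) + s2e
  Ztr <- rowsum(r, li)
  Vinv_r <- (r - (Htt %*% solve(S, Ztr))[li]) / s2e
  ghat_v <- as.numeric(Hvt %*% rowsum(Vinv_r, li))
  stats::setNames(ghat_v, validation_lines)
}
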