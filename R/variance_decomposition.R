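# Proportion of phenotypic variance explained by significant markers,
# added class by class (SNPs, then INDELs, then ORFS) with marginal
# F-test covariate selection under the mixed model.

#' Fixed-effect fitted values under the mixed model
#'
#' Coefficients are estimated by generalized least squares with `delta`
#' from a (RE)ML fit of the model carrying the same covariates; the fitted
#' values exclude the random effect (fixed part only).  With no covariates
#' the fit is the intercept, i.e. the phenotype mean.
#'
#' @param y phenotype vector
#' @param K kinship matrix
#' @param X covariate matrix (may be NULL)
#' @param reml passed to [fit_null()]
#' @return list: `yhat`, `beta` (including intercept), `delta`.
#' @export
fitted_fixed <- function(y, K, X = NULL, reml = TRUE) {
  n <- length(y)
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    return(list(yhat = rep(mean(y), n), beta = c(`(Intercept)` = mean(y)),
                delta = NA_real_))
  }
  X <- as.matrix(X)
  fit <- fit_null(y, K, X = X, reml = reml)
  R <- chol(K + diag(fit$delta, n))
  Xf <- cbind(1, X)
  Xw <- whiten(R, Xf)
  yw <- whiten(R, y)
  beta <- qr.coef(qr(Xw), yw)
  beta[is.na(beta)] <- 0
  list(yhat = as.numeric(Xf %*% beta), beta = beta, delta = fit$delta)
}

#' Proportion of variance explained
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed phenotypes
#' @param yhat fixed-effect fitted values
#' @return Numeric scalar.
#' @export
h2 <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("phenotype has zero variance")
  1 - sum((y - yhat)^2) / tss
}

#' Marginal forward selection and variance decomposition
#'
#' Candidate markers (genome-wide significant hits) are offered one at a
#' time, class by class in the order SNP, INDEL, ORFS and within each
#' class by ascending association p-value.  A candidate is kept only when
#' the F-test on the residual sums of squares of the nested whitened
#' fixed-effect fits (delta fixed from the null model) gives p below
#' `p_threshold`.  After each class the explained variance is computed
#' from a joint GLS refit of all covariates accepted so far: `h2_S` after
#' SNPs, `h2_SI` after INDELs, `h2_SIO` after ORFS; class increments are
#' the successive differences, clamped at zero (with a warning) so that
#' `h2_S + h2_I + h2_O = h2_SIO` holds exactly.
#'
#' Candidate genotype columns with missing values are mean-imputed for
#' this analysis (the association scan itself never imputes).
#'
#' @param y phenotype vector
#' @param K kinship matrix
#' @param cand_G matrix of candidate genotype columns (samples x markers)
#' @param cand_class character vector: `"snp"`, `"indel"` or `"orfs"` per
#'   column
#' @param cand_p association p-values per column (ordering within class)
#' @param p_threshold marginal F-test threshold (default 1e-4)
#' @param reml passed to the variance-component fits
#' @return list of class `decomposition`: `h2_S`, `h2_I`, `h2_O`,
#'   `h2_SI`, `h2_SIO`, `raw` (unclamped stage values), `selected`
#'   (data.frame: column, class, assoc p, marginal F p).
#' @export
marginal_select <- function(y, K, cand_G, cand_class, cand_p,
                            p_threshold = 1e-4, reml = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  cand_G <- as.matrix(cand_G)
  stopifnot(ncol(cand_G) == length(cand_class),
            ncol(cand_G) == length(cand_p))
  # mean-impute missing candidate genotypes
  for (k in seq_len(ncol(cand_G))) {
    miss <- is.na(cand_G[, k])
    if (any(miss)) cand_G[miss, k] <- mean(cand_G[, k], na.rm = TRUE)
  }
  null_fit <- fit_null(y, K, reml = reml)
  R <- chol(K + diag(null_fit$delta, n))
  yw <- whiten(R, y)
  onew <- whiten(R, rep(1, n))
  sel_idx <- integer(0)
  sel_rec <- list()
  rss_of <- function(cols) {
    Xw <- cbind(onew, if (length(cols)) whiten(R, cand_G[, cols, drop = FALSE]))
    sum(qr.resid(qr(Xw), yw)^2)
  }
  rss_cur <- rss_of(integer(0))
  stage_h2 <- c(snp = NA_real_, indel = NA_real_, orfs = NA_real_)
  for (cls in c("snp", "indel", "orfs")) {
    in_cls <- which(cand_class == cls)
    for (k in in_cls[order(cand_p[in_cls])]) {
      x <- cand_G[, k]
      if (stats::var(x) == 0) next
      if (length(sel_idx)) {
        r <- suppressWarnings(stats::cor(x, cand_G[, sel_idx, drop = FALSE]))
        if (any(!is.na(r) & abs(r) > 1 - 1e-12)) next   # perfect LD copy
      }
      p1 <- 2L + length(sel_idx)
      if (n - p1 < 2) break
      rss_new <- rss_of(c(sel_idx, k))
      if (rss_new >= rss_cur) next
      Fstat <- (rss_cur - rss_new) / (rss_new / (n - p1))
      pF <- stats::pf(Fstat, 1, n - p1, lower.tail = FALSE)
      if (pF < p_threshold) {
        sel_idx <- c(sel_idx, k)
        rss_cur <- rss_new
        sel_rec[[length(sel_rec) + 1L]] <-
          data.frame(column = k, class = cls, assoc_p = cand_p[k],
                     marginal_F_p = pF)
      }
    }
    ff <- fitted_fixed(y, K, if (length(sel_idx))
      cand_G[, sel_idx, drop = FALSE] else NULL, reml = reml)
    stage_h2[cls] <- h2(y, ff$yhat)
  }
  raw <- c(h2_S = unname(stage_h2["snp"]), h2_SI = unname(stage_h2["indel"]),
           h2_SIO = unname(stage_h2["orfs"]))
  h2_S <- max(0, raw[["h2_S"]])
  h2_I <- max(0, raw[["h2_SI"]] - h2_S)
  h2_O <- max(0, raw[["h2_SIO"]] - (h2_S + h2_I))
  if (h2_S < raw[["h2_S"]] - 1e-12 ||
      abs((h2_S + h2_I) - raw[["h2_SI"]]) > 1e-9 ||
      abs((h2_S + h2_I + h2_O) - raw[["h2_SIO"]]) > 1e-9) {
    if (raw[["h2_S"]] < 0 || raw[["h2_SI"]] < raw[["h2_S"]] ||
        raw[["h2_SIO"]] < raw[["h2_SI"]])
      warning("negative variance increment clamped to zero")
  }
  structure(list(h2_S = h2_S, h2_I = h2_I, h2_O = h2_O,
                 h2_SI = h2_S + h2_I, h2_SIO = h2_S + h2_I + h2_O,
                 raw = raw,
                 selected = if (length(sel_rec)) do.call(rbind, sel_rec)
                 else data.frame(column = integer(0), class = character(0),
                                 assoc_p = numeric(0),
                                 marginal_F_p = numeric(0))),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("variance decomposition: h2_S=%.3f h2_I=%.3f h2_O=%.3f (total %.3f)\n",
              x$h2_S, x$h2_I, x$h2_O, x$h2_SIO))
  invisible(x)
}
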