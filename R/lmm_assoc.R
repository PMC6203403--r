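# Linear mixed model association:  y = mu + x b + u + e,  Var(u) = sg2 K,
# Var(e) = se2 I, for inbred (haploid-coded) lines.  The variance ratio
# delta = se2/sg2 is estimated once under the null by REML on the spectral
# decomposition (EMMA scheme) and held fixed for per-marker generalized
# least squares tests (EMMAX scheme), with samples missing a marker's
# genotype dropped from that marker's test.

#' Balding-Nichols style kinship matrix
#'
#' `K[i,j]` is the average over markers of the allele-frequency
#' standardized cross product `(g_i - p)(g_j - p)/(p(1-p))`, taken over
#' markers non-missing in both samples, then adjusted to be positive
#' semidefinite by adding `(|min eigenvalue| + 1e-9) I` when needed.
#'
#' @param gm a `genotype_matrix` (typically SNPs)
#' @param flavor `"bn"` (default), `"ibs"` (identity-by-state), or
#'   `"identity"`
#' @return Symmetric PSD samples x samples matrix.
#' @export
kinship_bn <- function(gm, flavor = c("bn", "ibs", "identity")) {
  flavor <- match.arg(flavor)
  n <- nrow(gm$G)
  if (n < 2) stop("kinship needs at least two samples")
  if (flavor == "identity")
    return(diag(1, n, n) |> `dimnames<-`(list(rownames(gm$G), rownames(gm$G))))
  if (flavor == "ibs") return(psd_adjust(ibs_matrix(gm)))
  G <- gm$G
  p <- colMeans(G, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers for kinship")
  G <- G[, poly, drop = FALSE]; p <- p[poly]
  S <- sweep(sweep(G, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  obs <- !is.na(G)
  S[!obs] <- 0
  K <- tcrossprod(S) / tcrossprod(obs * 1)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(gm$G), rownames(gm$G))
  psd_adjust(K)
}

psd_adjust <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) K <- K + diag(abs(min(ev)) + 1e-9, nrow(K))
  K
}

#' Fit the null mixed model
#'
#' Estimates `delta = se2/sg2` by (RE)ML on the eigendecomposition of
#' `S (K + I) S` (`S` the projection off the fixed effects), scanning a
#' 100-point grid over `log delta` in [-10, 10] and refining the best
#' bracket with [stats::optimize()].
#'
#' @param y phenotype vector (no missing values)
#' @param K kinship matrix aligned with `y`
#' @param X optional covariate matrix (no intercept column; one is added)
#' @param reml use REML (default) or ML
#' @return list of class `lmm_fit`: `delta`, `sigma_g2`, `sigma_e2`,
#'   `h2 = 1/(1+delta)`, `loglik`, plus internals reused by
#'   [test_marker()].
#' @export
fit_null <- function(y, K, X = NULL, reml = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 samples")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (!all(dim(K) == n)) stop("K dimensions do not match y")
  Xf <- cbind(`(Intercept)` = rep(1, n), X)
  q <- qr(Xf)
  if (q$rank < ncol(Xf)) stop("fixed-effect matrix is rank deficient")
  # spectral decomposition of S (K + I) S restricted to the complement
  S <- diag(n) - Xf %*% solve(crossprod(Xf), t(Xf))
  eg <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  keep <- seq_len(n - ncol(Xf))
  lambda <- eg$values[keep] - 1
  lambda[lambda < -1 + 1e-12] <- -1 + 1e-12
  eta <- crossprod(eg$vectors[, keep, drop = FALSE], y)[, 1]
  egK <- if (!reml) eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ll <- function(logd) {
    d <- exp(logd)
    R <- sum(eta^2 / (lambda + d))
    if (reml) {
      nq <- n - ncol(Xf)
      0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(R)) - sum(log(lambda + d)))
    } else {
      0.5 * (n * (log(n / (2 * pi)) - 1 - log(R)) - sum(log(egK + d)))
    }
  }
  grid <- seq(-10, 10, length.out = 100)
  vals <- vapply(grid, ll, numeric(1))
  b <- which.max(vals)
  lo <- grid[max(1, b - 1)]; hi <- grid[min(length(grid), b + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  denom <- if (reml) n - ncol(Xf) else n
  sigma_g2 <- sum(eta^2 / (lambda + delta)) / denom
  structure(list(delta = delta, sigma_g2 = sigma_g2,
                 sigma_e2 = delta * sigma_g2, h2 = 1 / (1 + delta),
                 loglik = opt$objective, reml = reml, y = y, K = K, X = X,
                 n = n, cache = new.env(parent = emptyenv())),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: n=%d delta=%.4g sigma_g2=%.4g sigma_e2=%.4g h2=%.3f\n",
              x$n, x$delta, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

# Cholesky whitening of V = K + delta I restricted to `used`, memoized by
# missingness pattern so markers sharing a pattern share the factor.
whitener <- function(fit, used) {
  key <- paste0("p", paste(which(!used), collapse = ","))
  ch <- fit$cache[[key]]
  if (is.null(ch)) {
    V <- fit$K[used, used, drop = FALSE] + diag(fit$delta, sum(used))
    ch <- chol(V)
    fit$cache[[key]] <- ch
  }
  ch
}

whiten <- function(R, v) backsolve(R, v, transpose = TRUE)

#' Test one marker under the fitted mixed model
#'
#' Generalized least squares t-test of the marker effect with `delta`
#' fixed from the null fit; samples missing the marker's genotype are
#' excluded and the whitening factor for each missingness pattern is
#' memoized.  With an identity kinship this reproduces the ordinary
#' linear-regression test exactly.
#'
#' @param fit an `lmm_fit`
#' @param x marker genotypes aligned with the fit's samples (NA = missing)
#' @return list: `n_used`, `beta`, `se`, `statistic` (t), `p_value`
#'   (NA when the marker is monomorphic among used samples).
#' @export
test_marker <- function(fit, x) {
  used <- !is.na(x)
  nu <- sum(used)
  X0 <- fit$X
  p_fix <- 2L + if (is.null(X0)) 0L else ncol(X0)
  if (nu < p_fix + 1L || stats::var(x[used]) == 0)
    return(list(n_used = nu, beta = NA_real_, se = NA_real_,
                statistic = NA_real_, p_value = NA_real_))
  R <- whitener(fit, used)
  Xm <- cbind(1, if (is.null(X0)) NULL else X0[used, , drop = FALSE], x[used])
  Xw <- whiten(R, Xm)
  yw <- whiten(R, fit$y[used])
  f <- stats::lm.fit(Xw, yw)
  if (f$rank < ncol(Xm))
    return(list(n_used = nu, beta = NA_real_, se = NA_real_,
                statistic = NA_real_, p_value = NA_real_))
  df <- nu - ncol(Xm)
  rss <- sum(f$residuals^2)
  XtXi <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(rss / df * XtXi[ncol(Xm), ncol(Xm)])
  beta <- unname(f$coefficients[ncol(Xm)])
  tt <- beta / se
  list(n_used = nu, beta = beta, se = se, statistic = tt,
       p_value = 2 * stats::pt(-abs(tt), df))
}

#' Scan all markers of a genotype matrix
#'
#' @param gm a `genotype_matrix` whose rows align with `fit$y`
#' @param fit an `lmm_fit` from [fit_null()]
#' @return data.frame: marker metadata plus `n_used`, `beta`, `se`,
#'   `statistic`, `p_value`.
#' @export
assoc_scan <- function(gm, fit) {
  res <- lapply(seq_len(ncol(gm$G)), function(k) test_marker(fit, gm$G[, k]))
  out <- cbind(gm$markers,
               do.call(rbind, lapply(res, function(r)
                 data.frame(n_used = r$n_used, beta = r$beta, se = r$se,
                            statistic = r$statistic, p_value = r$p_value))))
  rownames(out) <- NULL
  out
}

#' Genome-wide significance thresholds
#'
#' Bonferroni: `alpha / n_tests`, where `n_tests` counts all markers
#' offered (pass a combined matrix for the integrated threshold over
#' SNPs + INDELs + ORFS).  Permutation: the phenotype vector is permuted
#' against the sample labels `n_perm` times, the genome-wide minimum
#' p-value recorded per permutation, and the empirical `alpha`-quantile of
#' those minima returned.  `delta` stays fixed from the null fit.
#'
#' @param gms a `genotype_matrix` or list of them (classes combined)
#' @param fit an `lmm_fit`
#' @param n_perm number of permutations (default 1000; fewer than 20
#'   warns)
#' @param alpha genome-wide significance level (default 0.05)
#' @param seed optional RNG seed for the permutations
#' @return list of class `threshold_set`: `bonferroni_p`, `permutation_p`,
#'   `n_tests`, `n_permutations`, `min_p` (the permutation minima).
#' @export
assoc_thresholds <- function(gms, fit, n_perm = 1000L, alpha = 0.05,
                             seed = NULL) {
  if (inherits(gms, "genotype_matrix")) gms <- list(gms)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 20) warning("fewer than 20 permutations: threshold unstable")
  if (!is.null(seed)) set.seed(seed)
  G <- do.call(cbind, lapply(gms, function(g) g$G))
  n_tests <- ncol(G)
  n <- fit$n
  Yp <- vapply(seq_len(n_perm), function(i) sample(fit$y), numeric(n))
  minp <- rep(1, n_perm)
  pattern <- apply(is.na(G), 2, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    cols <- which(pattern == pat)
    used <- rep(TRUE, n)
    if (nzchar(pat)) used[as.integer(strsplit(pat, ",")[[1]])] <- FALSE
    nu <- sum(used)
    if (nu < 4) next
    R <- whitener(fit, used)
    ones_w <- whiten(R, rep(1, nu))
    Yw <- whiten(R, Yp[used, , drop = FALSE])
    df <- nu - 2L
    for (k in cols) {
      xk <- G[used, k]
      if (stats::var(xk) == 0) next
      Xw <- cbind(ones_w, whiten(R, xk))
      XtXi <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
      if (is.null(XtXi)) next
      B <- XtXi %*% crossprod(Xw, Yw)
      E <- Yw - Xw %*% B
      rss <- colSums(E^2)
      xtxi <- XtXi[2, 2]
      tt <- B[2, ] / sqrt(rss / df * xtxi)
      p <- 2 * stats::pt(-abs(tt), df)
      minp <- pmin(minp, p)
    }
  }
  structure(list(bonferroni_p = alpha / n_tests,
                 permutation_p = unname(stats::quantile(minp, alpha, type = 1)),
                 n_tests = n_tests, n_permutations = n_perm, min_p = minp),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: bonferroni=%.3g permutation=%.3g (%d tests, %d perms)\n",
              x$bonferroni_p, x$permutation_p, x$n_tests, x$n_permutations))
  invisible(x)
}

#' Manhattan plot of association results
#' @param results data.frame from [assoc_scan()]
#' @param threshold optional genome-wide threshold p-value (dashed line)
#' @param ... passed to [plot()]
#' @return Invisibly, the plotted data.
#' @export
plot_manhattan <- function(results, threshold = NULL, ...) {
  r <- results[!is.na(results$p_value), , drop = FALSE]
  chr <- factor(r$chrom)
  off <- c(0, cumsum(tapply(r$pos, chr, max, na.rm = TRUE)))
  x <- r$pos + off[as.integer(chr)]
  plot(x, -log10(r$p_value), pch = 20, col = as.integer(chr) %% 2 + 1,
       xlab = "genome position", ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold)) graphics::abline(h = -log10(threshold), lty = 2)
  invisible(data.frame(x = x, y = -log10(r$p_value)))
}

#' Quantile-quantile plot of association p-values
#' @param results data.frame from [assoc_scan()]
#' @param ... passed to [plot()]
#' @return Invisibly, the plotted data.
#' @export
plot_qq <- function(results, ...) {
  p <- sort(results$p_value[!is.na(results$p_value)])
  expd <- (seq_along(p) - 0.5) / length(p)
  plot(-log10(expd), -log10(p), pch = 20,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(expected = -log10(expd), observed = -log10(p)))
}
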