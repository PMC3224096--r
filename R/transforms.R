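#' Generalized-log (glog) transform
#'
#' `glog(x, alpha, lambda) = log2(e) * ln(x - alpha + sqrt((x - alpha)^2 + lambda))`.
#' The natural-log value is multiplied by `log2(e)` so that the result is on
#' the log2 scale and directly comparable with a plain log2 transform.  The
#' function is defined and finite for every finite `x`, including negative
#' corrected intensities, is strictly increasing, and converges to
#' `log2(x)` at high intensities.  With `alpha = 0, lambda = 1` it equals
#' `log2(e) * arcsinh(x)`.
#'
#' @param x numeric vector (AFU; may be negative).
#' @param alpha offset (AFU, >= 0).
#' @param lambda curvature (AFU^2, > 0).
#' @return numeric vector on the log2 scale.
#' @export
glog <- function(x, alpha = 0, lambda = 1) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  z <- x - alpha
  ## z + sqrt(z^2 + lambda) loses precision for z << 0; use the conjugate
  s <- sqrt(z^2 + lambda)
  arg <- ifelse(z >= 0, z + s, lambda / (s - z))
  log2(exp(1)) * log(arg)
}

#' Parameters of the glog transform
#'
#' @param alpha offset (AFU, >= 0).
#' @param lambda curvature (AFU^2, > 0).
#' @param loglik converged profile log-likelihood (optional).
#' @return list of class `glog_params`.
#' @export
glog_params <- function(alpha, lambda, loglik = NA_real_) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, lambda = lambda, loglik = loglik),
            class = "glog_params")
}

#' Log2 transform of a corrected matrix
#'
#' Entry-wise log2; entries that are zero or negative (possible after
#' standard subtraction) become missing.
#'
#' @param corrected a `corrected_matrix`.
#' @return `transformed_matrix` with `transform = "log2"`.
#' @export
log2_transform <- function(corrected) {
  v <- corrected$values
  out <- ifelse(is.finite(v) & v > 0, suppressWarnings(log2(v)), NA_real_)
  transformed_matrix(out, corrected$design, "log2",
                     correction = corrected$method)
}

#' Glog transform of a corrected matrix
#'
#' @param corrected a `corrected_matrix`.
#' @param params a [glog_params()]; `NULL` estimates them from the matrix
#'   with [estimate_glog_params()].
#' @return `transformed_matrix` with `transform = "glog"`; never missing.
#' @export
glog_transform <- function(corrected, params = NULL) {
  if (is.null(params)) params <- estimate_glog_params(corrected)
  stopifnot(inherits(params, "glog_params"))
  out <- glog(corrected$values, params$alpha, params$lambda)
  transformed_matrix(out, corrected$design, "glog", glog_params = params,
                     correction = corrected$method)
}

## profile log-likelihood of the transform-both-sides normal model:
## transformed replicates within each gene x condition group share a mean,
## residual variance is pooled across groups, and the Jacobian
## J(x) = 1/sqrt((x-alpha)^2 + lambda) accounts for the change of scale.
glog_tbs_loglik <- function(x, group, alpha, lambda) {
  z <- x - alpha
  tx <- ifelse(z >= 0, z + sqrt(z^2 + lambda),
               lambda / (sqrt(z^2 + lambda) - z))
  tx <- log(tx)
  n_g <- tabulate(group)
  keep <- n_g[group] >= 2
  if (!any(keep)) return(-Inf)
  tk <- tx[keep]; gk <- as.character(group[keep])
  sums <- rowsum(tk, gk)
  cnt <- rowsum(rep(1, length(tk)), gk)
  means <- sums / cnt
  resid <- tk - means[match(gk, rownames(means)), 1]
  N <- length(tk)
  ss <- sum(resid^2)
  df <- N - nrow(means)
  if (df <= 0) return(-Inf)
  s2 <- ss / df
  # degenerate: within-group variance zero up to floating-point rounding
  if (s2 <= .Machine$double.eps^1.5 * mean(tk^2)) return(NA_real_)
  -0.5 * sum(log(z[keep]^2 + lambda)) - (N / 2) * log(s2)
}

#' Estimate glog parameters by transform-both-sides maximum likelihood
#'
#' Chooses `(alpha, lambda)` so that, after the glog transform, replicate
#' measurements within each gene-by-condition group are as close to
#' homoscedastic normal as the data allow: the criterion is the profile
#' log-likelihood `sum(log J(x)) - (N/2) * log(pooled within-group variance)`
#' with Jacobian `J(x) = 1/sqrt((x - alpha)^2 + lambda)`.  A coarse search
#' over a log-spaced lambda grid (and alpha over `[0, 5th percentile of x]`)
#' is refined by simplex descent.
#'
#' @param corrected a `corrected_matrix` (spot- or gene-level) with at least
#'   2 arrays per condition; spot rows are grouped by gene.
#' @param fix_alpha optional fixed offset; only lambda is then estimated.
#' @return a `glog_params` with the converged profile log-likelihood.
#' @export
estimate_glog_params <- function(corrected, fix_alpha = NULL) {
  v <- corrected$values
  design <- corrected$design
  genes <- if (inherits(corrected, "corrected_matrix") ||
               inherits(corrected, "transformed_matrix")) {
    row_genes(v)
  } else {
    rownames(v)
  }
  cond <- design$condition[match(colnames(v), design$array_id)]
  x <- as.vector(v)
  group_lab <- paste(rep(genes, times = ncol(v)),
                     rep(cond, each = nrow(v)), sep = "\r")
  ok <- is.finite(x)
  x <- x[ok]; group_lab <- group_lab[ok]
  group <- factor(group_lab)
  n_per <- table(group)
  if (!any(n_per >= 2)) {
    stop("every gene x condition group has fewer than 2 replicates",
         call. = FALSE)
  }
  if (length(unique(genes)) < 50) {
    stop("need at least 50 genes with replicates to estimate glog parameters",
         call. = FALSE)
  }
  vx <- stats::var(x)
  lambda_grid <- vx * 10^seq(-4, 1, length.out = 11)
  alpha_hi <- max(0, stats::quantile(x, 0.05, names = FALSE))
  alpha_grid <- if (is.null(fix_alpha)) {
    unique(seq(0, alpha_hi, length.out = 4))
  } else {
    fix_alpha
  }
  obj <- function(alpha, lambda) {
    ll <- glog_tbs_loglik(x, group, alpha, lambda)
    if (is.na(ll)) {
      stop("degenerate fit: zero within-group variance of transformed values",
           call. = FALSE)
    }
    ll
  }
  grid <- expand.grid(alpha = alpha_grid, lambda = lambda_grid)
  ll_grid <- mapply(obj, grid$alpha, grid$lambda)
  start <- grid[which.max(ll_grid), ]
  if (is.null(fix_alpha)) {
    neg <- function(th) {
      if (th[1] < 0) return(.Machine$double.xmax)
      -obj(th[1], exp(th[2]))
    }
    fit <- stats::optim(c(start$alpha, log(start$lambda)), neg,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-9))
    glog_params(max(fit$par[1], 0), exp(fit$par[2]), loglik = -fit$value)
  } else {
    neg <- function(th) -obj(fix_alpha, exp(th))
    fit <- stats::optim(log(start$lambda), neg, method = "Brent",
                        lower = log(start$lambda) - 8,
                        upper = log(start$lambda) + 8)
    glog_params(fix_alpha, exp(fit$par), loglik = -fit$value)
  }
}
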