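#' Standard background correction (local subtraction)
#'
#' Subtracts the local background intensity from the foreground intensity of
#' every spot.  Negative corrected intensities are preserved: they occur
#' whenever the foreground falls below the local background and are the
#' reason the log2 pipeline produces missing values.
#'
#' @param dataset a `spot_dataset`.
#' @return spot-level `corrected_matrix` with `method = "standard"`.
#' @export
correct_standard <- function(dataset) {
  F <- spot_matrix(dataset, "F")
  B <- spot_matrix(dataset, "B")
  corrected_matrix(F - B, array_design(dataset), "standard")
}

#' No background correction
#'
#' The corrected intensities equal the foreground intensities; the local
#' background is ignored entirely.
#'
#' @param dataset a `spot_dataset`.
#' @return spot-level `corrected_matrix` with `method = "none"`.
#' @export
correct_none <- function(dataset) {
  corrected_matrix(spot_matrix(dataset, "F"), array_design(dataset), "none")
}

#' Edwards smooth monotone background correction
#'
#' Background is subtracted when the difference `F - B` exceeds a small
#' positive threshold `delta`; below the threshold, subtraction is replaced
#' by the smooth monotone positive function `delta * exp(1 - (B + delta)/F)`.
#' The two branches agree at `F - B = delta`, the result is strictly
#' positive and strictly increasing in `F` for fixed `B`, and it is defined
#' even when `F <= B` — so the downstream log2 transform never produces
#' missing values.
#'
#' @param dataset a `spot_dataset` with strictly positive foregrounds.
#' @param delta threshold (AFU, > 0): a scalar, or a vector named by
#'   array id; `NULL` uses [default_edwards_delta()].
#' @return spot-level `corrected_matrix` with `method = "edwards"`.
#' @export
correct_edwards <- function(dataset, delta = NULL) {
  F <- spot_matrix(dataset, "F")
  B <- spot_matrix(dataset, "B")
  if (any(F[is.finite(F)] <= 0)) {
    stop("Edwards correction requires strictly positive foreground intensities",
         call. = FALSE)
  }
  if (is.null(delta)) delta <- default_edwards_delta(dataset)
  if (any(delta <= 0)) stop("delta must be > 0", call. = FALSE)
  if (length(delta) == 1) {
    delta_mat <- delta
  } else {
    if (!all(colnames(F) %in% names(delta))) {
      stop("per-array delta must be named by array_id", call. = FALSE)
    }
    delta_mat <- matrix(delta[colnames(F)], nrow(F), ncol(F), byrow = TRUE)
  }
  vals <- edwards_values(F, B, delta_mat)
  corrected_matrix(vals, array_design(dataset), "edwards",
                   params = list(delta = delta))
}

## vectorized Edwards correction on raw values; the smooth branch can
## underflow for F near 0, so keep the output strictly positive
edwards_values <- function(F, B, delta) {
  d <- F - B
  pmax(ifelse(d > delta, d, delta * exp(1 - (B + delta) / F)),
       .Machine$double.xmin)
}

#' Default Edwards threshold
#'
#' Per array, the smallest strictly positive difference `F - B` on that
#' array; the threshold is then as small as the data allow, so subtraction
#' is used wherever it yields a positive value.
#'
#' @param dataset a `spot_dataset`.
#' @return numeric vector of thresholds named by array id.
#' @export
default_edwards_delta <- function(dataset) {
  d <- spot_matrix(dataset, "F") - spot_matrix(dataset, "B")
  vapply(colnames(d), function(a) {
    pos <- d[, a][is.finite(d[, a]) & d[, a] > 0]
    if (length(pos) == 0) {
      stop(sprintf("array %s has no spot with F > B; cannot set delta", a),
           call. = FALSE)
    }
    min(pos)
  }, numeric(1))
}

#' Parameters of the normal + exponential convolution model
#'
#' Observed (standard-corrected) intensity = Normal(mu, sigma^2) background
#' noise + Exponential(mean alpha_signal) true signal.
#'
#' @param mu background-noise mean (AFU).
#' @param sigma background-noise SD (AFU, > 0).
#' @param alpha_signal exponential signal mean (AFU, > 0).
#' @param loglik converged log-likelihood (optional).
#' @return list of class `normexp_params`.
#' @export
normexp_params <- function(mu, sigma, alpha_signal, loglik = NA_real_) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (alpha_signal <= 0) stop("alpha_signal must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, alpha_signal = alpha_signal,
                 loglik = loglik),
            class = "normexp_params")
}

## log-density of the normal+exponential convolution
dnormexp_log <- function(x, mu, sigma, alpha) {
  -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
    stats::pnorm((x - mu) / sigma - sigma / alpha, log.p = TRUE)
}

#' Fit the normal + exponential convolution model by maximum likelihood
#'
#' The likelihood is maximized over `(mu, log sigma, log alpha_signal)` by
#' simplex descent from a method-of-moments start (third central moment for
#' the exponential mean, remaining variance for sigma), with deterministic
#' scale-jittered restarts since the likelihood can be flat in sigma.
#'
#' @param x numeric vector of standard-corrected (or raw foreground)
#'   intensities; at least 100 finite values with positive variance.
#' @param n_restarts number of jittered restarts beyond the moment start.
#' @return a `normexp_params` with the converged log-likelihood.
#' @export
fit_normexp <- function(x, n_restarts = 4) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 finite values", call. = FALSE)
  v <- stats::var(x)
  if (v <= 0) stop("input has zero variance", call. = FALSE)
  ## fit on standardized data for conditioning; back-transform at the end
  ctr <- stats::median(x)
  scl <- sqrt(v)
  z <- (x - ctr) / scl
  m <- mean(z)
  m3 <- mean((z - m)^3)
  alpha0 <- max((max(m3, 0) / 2)^(1/3), 0.1)
  sigma0 <- sqrt(max(1 - alpha0^2, 0.01))
  mu0 <- m - alpha0
  nll <- function(th) {
    if (any(abs(th) > 50)) return(.Machine$double.xmax)
    val <- -sum(dnormexp_log(z, th[1], exp(th[2]), exp(th[3])))
    if (!is.finite(val)) .Machine$double.xmax else val
  }
  start0 <- c(mu0, log(sigma0), log(alpha0))
  jitter <- list(c(0, 0, 0), c(0, log(0.5), 0), c(0, log(2), 0),
                 c(0, 0, log(0.5)), c(0, 0, log(2)),
                 c(-sigma0, log(0.5), log(2)))
  polish <- function(par) {
    fit <- stats::optim(par, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    for (k in 1:4) {
      if (fit$convergence == 0) break
      fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
    }
    fit
  }
  best <- NULL
  for (j in jitter[seq_len(min(n_restarts + 1, length(jitter)))]) {
    fit <- try(polish(start0 + j), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$value >= .Machine$double.xmax) next
    if (is.null(best) ||
        (fit$convergence == 0 && best$convergence != 0) ||
        (fit$convergence == best$convergence && fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("normexp fit failed from every start", call. = FALSE)
  if (best$convergence != 0) {
    stop(sprintf(paste0("normexp fit did not converge; best iterate ",
                        "mu=%.4g sigma=%.4g alpha=%.4g"),
                 ctr + scl * best$par[1], scl * exp(best$par[2]),
                 scl * exp(best$par[3])),
         call. = FALSE)
  }
  ## back-transform; log-likelihood picks up the Jacobian -n*log(scl)
  normexp_params(ctr + scl * best$par[1], scl * exp(best$par[2]),
                 scl * exp(best$par[3]),
                 loglik = -best$value - length(z) * log(scl))
}

#' Normexp background correction (posterior mean of the signal)
#'
#' Returns `E[S | X = x]` under the convolution model `X = N + S`,
#' `N ~ Normal(mu, sigma^2)`, `S ~ Exponential(mean alpha_signal)`:
#' `mu_sf + sigma * phi(mu_sf/sigma) / Phi(mu_sf/sigma)` with
#' `mu_sf = x - mu - sigma^2/alpha_signal`.  The normal density/CDF ratio is
#' evaluated on the log scale, so the far left tail (`mu_sf/sigma` below -5)
#' is numerically stable and the output is strictly positive for any finite
#' input.
#'
#' @param x numeric vector of observed intensities.
#' @param params a `normexp_params`.
#' @return numeric vector of strictly positive corrected intensities.
#' @export
correct_normexp <- function(x, params) {
  stopifnot(inherits(params, "normexp_params"))
  mu_sf <- x - params$mu - params$sigma^2 / params$alpha_signal
  t <- mu_sf / params$sigma
  out <- mu_sf + params$sigma *
    exp(stats::dnorm(t, log = TRUE) - stats::pnorm(t, log.p = TRUE))
  pmax(out, .Machine$double.xmin)
}

## apply normexp per array to a standard-corrected spot matrix
correct_normexp_dataset <- function(dataset) {
  std <- correct_standard(dataset)
  vals <- std$values
  fits <- lapply(colnames(vals), function(a) fit_normexp(vals[, a]))
  names(fits) <- colnames(vals)
  for (a in colnames(vals)) {
    vals[, a] <- correct_normexp(vals[, a], fits[[a]])
  }
  corrected_matrix(vals, array_design(dataset), "normexp", params = fits)
}

#' Apply a background-correction method to a dataset
#'
#' @param dataset a `spot_dataset`.
#' @param method `"standard"`, `"none"`, `"edwards"` or `"normexp"`.
#' @param edwards_delta optional threshold forwarded to [correct_edwards()].
#' @return spot-level `corrected_matrix`.
#' @export
correct_background <- function(dataset,
                               method = c("standard", "none", "edwards",
                                          "normexp"),
                               edwards_delta = NULL) {
  method <- match.arg(method)
  switch(method,
         standard = correct_standard(dataset),
         none = correct_none(dataset),
         edwards = correct_edwards(dataset, edwards_delta),
         normexp = correct_normexp_dataset(dataset))
}
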