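test_that("standard subtraction preserves negative values; none ignores B", {
  ds <- tiny_dataset(diffs = matrix(c(300, -50, 2, 300, -50, 2,
                                      300, -50, 2, 300, -50, 2), 3, 4))
  std <- correct_standard(ds)
  expect_equal(sort(unique(as.vector(std$values))), c(-50, 2, 300))
  none <- correct_none(ds)
  expect_equal(none$values, spotglow:::spot_matrix(ds, "F"))

  ds0 <- tiny_dataset(B = 0)
  expect_equal(correct_standard(ds0)$values,
               spotglow:::spot_matrix(ds0, "F"))

  # no-background output is invariant to any modification of B
  sp <- ds$spots
  sp$B <- 57
  sp$F <- pmax(sp$F, 0)
  ds_b <- spot_dataset(sp, 2)
  expect_equal(correct_none(ds_b)$values, none$values)
})

test_that("Edwards correction follows the smooth monotone contract", {
  # subtraction branch, continuity at the joint, and the smooth branch
  e <- function(F, B, delta) {
    d <- tiny_dataset(diffs = matrix(F - B, 3, 4), B = B)
    correct_edwards(d, delta)$values[1, 1]
  }
  expect_equal(e(500, 200, 100), 300)
  expect_equal(e(300, 200, 100), 100)              # F - B == delta
  expect_equal(e(250, 200, 100), 100 * exp(1 - 300 / 250), tolerance = 1e-12)
  expect_equal(100 * exp(1 - 300 / 250), 81.87308, tolerance = 1e-6)

  # strictly positive and strictly increasing in F for fixed B
  Fs <- seq(10, 1000, by = 5)
  vals <- spotglow:::edwards_values(Fs, 400, 50)
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))

  # continuity across the threshold: the two branches agree at the joint
  B <- 400; delta <- 50
  F0 <- B + delta
  expect_equal(F0 - B, delta * exp(1 - (B + delta) / F0), tolerance = 1e-12)
  left <- spotglow:::edwards_values(F0 - 1e-10, B, delta)
  right <- spotglow:::edwards_values(F0 + 1e-10, B, delta)
  expect_lt(abs(left - right), 1e-9)

  expect_error(correct_edwards(tiny_dataset(B = 0, diffs = matrix(0, 3, 4))),
               "positive foreground")
})

test_that("Edwards approaches standard subtraction as delta shrinks", {
  ds <- tiny_dataset(diffs = matrix(c(300, 120, 40), 3, 4))
  std <- correct_standard(ds)$values
  for (delta in c(10, 1, 1e-3)) {
    ed <- correct_edwards(ds, delta)$values
    expect_lt(max(abs(ed - std)), delta)
  }
})

test_that("default Edwards delta is the smallest positive difference", {
  ds <- tiny_dataset(diffs = matrix(c(300, -50, 2), 3, 4))
  expect_equal(unname(default_edwards_delta(ds)), rep(2, 4))
  ds_pos <- tiny_dataset(diffs = matrix(c(300, 10, 55), 3, 4))
  expect_equal(unname(default_edwards_delta(ds_pos)), rep(10, 4))
  ds_neg <- tiny_dataset(diffs = matrix(c(-5, -50, 0), 3, 4))
  expect_error(default_edwards_delta(ds_neg), "no spot with F > B")
})

test_that("normexp maximum likelihood agrees with an independent fitter", {
  set.seed(42)
  x <- stats::rnorm(20000, 100, 15) + stats::rexp(20000, 1 / 200)
  f <- fit_normexp(x)
  expect_lt(abs(f$mu - 100) / 100, 0.05)
  expect_lt(abs(f$sigma - 15) / 15, 0.05)
  expect_lt(abs(f$alpha_signal - 200) / 200, 0.05)

  lf <- limma::normexp.fit(x, method = "mle")
  expect_equal(f$mu, lf$par[1], tolerance = 1e-3)
  expect_equal(f$sigma, exp(lf$par[2]), tolerance = 1e-3)
  expect_equal(f$alpha_signal, exp(lf$par[3]), tolerance = 1e-3)

  # the fit is at least as good as the truth on the same sample
  ll_true <- sum(spotglow:::dnormexp_log(x, 100, 15, 200))
  expect_gte(f$loglik, ll_true)

  expect_error(fit_normexp(rep(5, 200)), "zero variance")
  expect_error(fit_normexp(x[1:50]), "at least 100")
})

test_that("normexp correction is positive, monotone and tail-stable", {
  par <- normexp_params(0, 1, 1)
  xs <- c(-50, -5, 0, 1, 10, 1e4)
  out <- correct_normexp(xs, par)
  expect_true(all(out > 0))
  expect_true(all(diff(out) > 0))

  # far right tail: posterior mean converges to x - mu - sigma^2/alpha
  par2 <- normexp_params(100, 15, 200)
  x_far <- 100 + 50 * 15
  expect_equal(correct_normexp(x_far, par2),
               x_far - 100 - 15^2 / 200, tolerance = 1e-6)

  # matches limma's evaluation of the same posterior mean
  expect_equal(correct_normexp(xs, par),
               limma::normexp.signal(c(0, 0, 0), xs), tolerance = 1e-10)
})

test_that("normexp correction matches quadrature of E[S | X = x]", {
  quad <- function(x, mu, sigma, alpha) {
    lo <- max(0, x - mu - 50 * sigma)
    hi <- max(x - mu + 50 * sigma, 50 * sigma)
    num <- stats::integrate(function(s)
      s * stats::dexp(s, 1 / alpha) * stats::dnorm(x - mu - s, 0, sigma),
      lo, hi, rel.tol = 1e-12)$value
    den <- stats::integrate(function(s)
      stats::dexp(s, 1 / alpha) * stats::dnorm(x - mu - s, 0, sigma),
      lo, hi, rel.tol = 1e-12)$value
    num / den
  }
  par <- normexp_params(0, 20, 100)
  xs <- c(-20, 0, 10, 50, 200, 1000)
  ours <- correct_normexp(xs, par)
  oracle <- vapply(xs, quad, numeric(1), mu = 0, sigma = 20, alpha = 100)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("correcting a dataset with normexp gives positive spot values", {
  sim <- simulate_dataset(small_config(seed = 13))
  cm <- correct_background(sim$dataset, "normexp")
  expect_true(all(cm$values > 0))
  expect_equal(dim(cm$values), dim(spotglow:::spot_matrix(sim$dataset, "F")))
  expect_named(cm$params, array_design(sim$dataset)$array_id)
})
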