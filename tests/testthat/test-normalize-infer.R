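test_that("global median normalization equalizes medians and nothing else", {
  m <- gene_matrix(matrix(c(1, 2, 3, 11, 12, 13, 5, 6, 7, 8, 9, 10), 3, 4),
                   c("A", "A", "B", "B"))
  norm <- global_median_normalize(m)
  med <- apply(norm$values, 2, stats::median)
  expect_equal(unname(diff(range(med))), 0)
  # within-array differences unchanged
  expect_equal(apply(norm$values, 2, diff), apply(m$values, 2, diff),
               tolerance = 1e-12)
  # idempotent
  expect_equal(global_median_normalize(norm)$values, norm$values)

  m$values[, 2] <- NA_real_
  expect_error(global_median_normalize(m), "no finite value")
})

test_that("replicate-spot averaging uses the available spots", {
  v <- matrix(c(1, 2, 3, 1, NA, 3, NA, NA, NA, 4, 4, 4), 3, 4,
              dimnames = list(paste0("g1#", 1:3), NULL))
  design <- data.frame(array_id = paste0("a", 1:4), site = "s",
                       condition = c("A", "A", "B", "B"))
  colnames(v) <- design$array_id
  tm <- transformed_matrix(v, design, "log2")
  out <- average_replicate_spots(tm)
  expect_equal(as.vector(out$values), c(2, 2, NA, 4))
  expect_equal(rownames(out$values), "g1")
})

test_that("two-group fits match hand computation and contracts", {
  m <- gene_matrix(matrix(c(0, 2, 5, 9), 1, 4), c("A", "A", "B", "B"))
  f <- fit_linear_model(m)
  expect_equal(f$logfc, 6)
  expect_equal(f$s2, 5)     # ((0-1)^2+(2-1)^2+(5-7)^2+(9-7)^2)/2
  expect_equal(f$df, 2)
  expect_equal(f$v, 1)

  m2 <- gene_matrix(matrix(c(1, 1, 1, 1, 1, 3, 3, 3, 3, 3,
                             1, 1, NA, NA, 2, 4, NA, NA, NA, NA), 2, 10,
                           byrow = TRUE),
                    rep(c("A", "B"), each = 5))
  f2 <- fit_linear_model(m2)
  expect_equal(f2$logfc, c(2, NA))
  expect_equal(f2$s2[1], 0)
  expect_true(is.na(f2$s2[2]))  # a single finite B value is not fittable
})

test_that("moderation with d0 = 0 is the classical pooled t-test", {
  set.seed(5)
  v <- matrix(stats::rnorm(50 * 8, 0, rep(stats::runif(50, 0.2, 2), 8)), 50, 8)
  m <- gene_matrix(v, rep(c("A", "B"), each = 4))
  de <- ebayes_moderate(fit_linear_model(m), prior = ebayes_prior(0, 1))
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(v[i, 5:8], v[i, 1:4], var.equal = TRUE)
    expect_equal(de$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$logfc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("a dominating prior pins every posterior variance at s0", {
  set.seed(6)
  v <- matrix(stats::rnorm(40 * 6), 40, 6)
  m <- gene_matrix(v, rep(c("A", "B"), each = 3))
  fits <- fit_linear_model(m)
  de <- ebayes_moderate(fits, prior = ebayes_prior(1e12, 0.7))
  s2_post <- (de$logfc / de$t_stat)^2 / fits$v
  expect_equal(s2_post, rep(0.7, 40), tolerance = 1e-6)
})

test_that("prior estimation recovers d0 and matches limma exactly", {
  set.seed(7)
  ng <- 2000
  sg2 <- 0.05 * 4 / stats::rchisq(ng, 4)     # scaled inverse chi-square, d0=4
  v <- matrix(stats::rnorm(ng * 10, 0, rep(sqrt(sg2), 10)), ng, 10)
  m <- gene_matrix(v, rep(c("A", "B"), each = 5))
  fits <- fit_linear_model(m)
  de <- ebayes_moderate(fits)
  prior <- attr(de, "prior")
  expect_gt(prior$d0, 2)
  expect_lt(prior$d0, 8)

  lfit <- limma::eBayes(limma::lmFit(v, cbind(1, rep(c(0, 1), each = 5))))
  expect_equal(prior$d0, lfit$df.prior, tolerance = 1e-9)
  expect_equal(prior$s0_sq, lfit$s2.prior, tolerance = 1e-9)
  expect_equal(de$t_stat, unname(lfit$t[, 2]), tolerance = 1e-9)
  expect_equal(de$p, unname(lfit$p.value[, 2]), tolerance = 1e-9)
})

test_that("adding a constant to one array leaves fold-changes unchanged", {
  set.seed(8)
  v <- matrix(stats::rnorm(60 * 6, 8), 60, 6)
  m1 <- gene_matrix(v, rep(c("A", "B"), each = 3))
  v2 <- v; v2[, 4] <- v2[, 4] + 3.7
  m2 <- gene_matrix(v2, rep(c("A", "B"), each = 3))
  f1 <- fit_linear_model(global_median_normalize(m1))
  f2 <- fit_linear_model(global_median_normalize(m2))
  expect_equal(f1$logfc, f2$logfc, tolerance = 1e-12)
})

test_that("noise-free pipelines recover the truth up to a constant", {
  cfg <- small_config(seed = 3, eta_sd = 0, eps_sd = 0,
                      background_spot_sd = 0, n_arrays_per_condition = 2)
  sim <- simulate_dataset(cfg)
  de <- run_pipeline(sim$dataset, "standard", "log2",
                     prior = ebayes_prior(0, 1))
  delta <- de$logfc - sim$truth$true_logfc[match(de$gene_id,
                                                 sim$truth$gene_id)]
  expect_lt(diff(range(delta)), 1e-9)

  cfg0 <- small_config(seed = 3, eta_sd = 0, eps_sd = 0,
                       background_spot_sd = 0, prop_de = 0,
                       n_arrays_per_condition = 2)
  sim0 <- simulate_dataset(cfg0)
  de0 <- run_pipeline(sim0$dataset, "standard", "log2",
                      prior = ebayes_prior(0, 1))
  expect_equal(de0$logfc, rep(0, nrow(de0)), tolerance = 1e-9)
})

test_that("all eight preprocessing combinations complete on one dataset", {
  sim <- simulate_dataset(small_config(seed = 14))
  grid <- method_grid()
  n_genes <- length(unique(sim$dataset$spots$gene_id))
  for (i in seq_len(nrow(grid))) {
    de <- run_pipeline(sim$dataset, grid$correction[i], grid$transform[i])
    expect_equal(nrow(de), n_genes)
    expect_identical(attr(de, "correction"), grid$correction[i])
    # positive corrections + log2, and glog, never produce missing results
    if (grid$transform[i] == "glog" ||
        grid$correction[i] %in% c("edwards", "normexp", "none")) {
      expect_false(anyNA(de$logfc))
    }
  }
})

test_that("hybrid combination takes fold-changes from log2, p from glog", {
  sim <- simulate_dataset(small_config(seed = 15))
  corrected <- correct_background(sim$dataset, "edwards")
  de_l <- spotglow:::run_pipeline_corrected(sim$dataset, corrected, "log2",
                                            NULL, NULL)
  de_g <- spotglow:::run_pipeline_corrected(sim$dataset, corrected, "glog",
                                            NULL, NULL)
  h <- hybrid_combine(de_l, de_g)
  expect_equal(h$logfc, de_l$logfc)
  expect_equal(h$ref_intensity, de_l$ref_intensity)
  expect_equal(h$p, de_g$p)
  expect_equal(h$t_stat, de_g$t_stat)
  expect_identical(attr(h, "transform"), "hybrid")

  # identity case
  hh <- hybrid_combine(de_g, de_g)
  expect_equal(hh$p, de_g$p)
  expect_equal(hh$logfc, de_g$logfc)

  # contract violations
  expect_error(hybrid_combine(de_l[-1, ], de_g), "gene sets")
  de_other <- run_pipeline(sim$dataset, "standard", "glog")
  expect_error(hybrid_combine(de_l, de_other), "corrections differ")

  # one-call interface reproduces the combination
  h2 <- run_pipeline(sim$dataset, "edwards", "hybrid")
  expect_equal(h2$logfc, h$logfc)
  expect_equal(h2$p, h$p)
})
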