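test_that("reference intensity is the minimum condition mean after standard+log2", {
  # F - B = 2^10.3 on A arrays, 2^8.1 on B arrays, for every gene
  ds <- tiny_dataset(diffs = matrix(rep(c(2^10.3, 2^10.3, 2^8.1, 2^8.1),
                                        each = 3), 3, 4))
  ref <- reference_intensity(ds)
  expect_equal(unname(ref), rep(8.1, 3), tolerance = 1e-12)

  # equal condition means
  ds_eq <- tiny_dataset(diffs = matrix(2^5, 3, 4))
  expect_equal(unname(reference_intensity(ds_eq)), rep(5, 3))

  # one condition entirely non-positive after correction -> missing
  ds_neg <- tiny_dataset(diffs = matrix(rep(c(100, 100, -5, -5), each = 3),
                                        3, 4))
  expect_true(all(is.na(reference_intensity(ds_neg))))
})

test_that("fold-change compression follows the gold-minus-platform convention", {
  de <- data.frame(gene_id = c("g1", "g2", "g3"), logfc = c(1, 2, -3),
                   t_stat = 1, p = 0.5, ref_intensity = c(5, 8, 11))
  class(de) <- c("de_result", "data.frame")
  gold <- gold_standard(data.frame(gene_id = c("g1", "g2", "g3"),
                                   logfc_gold = c(6, 2, -2),
                                   p_gold = c(1e-9, 0.5, 1e-4)))
  cmp <- compression_per_gene(de, gold)
  expect_equal(cmp$compression, c(5, 0, -1))
  expect_equal(cmp$ref_intensity, c(5, 8, 11))

  # compression of a method against itself is identically zero
  self_gold <- gold_standard(data.frame(gene_id = de$gene_id,
                                        logfc_gold = de$logfc,
                                        p_gold = de$p))
  expect_equal(compression_per_gene(de, self_gold)$compression, rep(0, 3))

  de_na <- de; de_na$logfc <- NA_real_
  expect_error(compression_per_gene(de_na, gold), "no shared gene")
})

test_that("lowess curve is exact on constants, near-linear data, and robust", {
  x <- seq(0, 1, length.out = 200)
  expect_equal(lowess_curve(x, rep(4, 200))$y, rep(4, 200))

  set.seed(31)
  y <- 2 * x + stats::rnorm(200, 0, 0.01)
  f <- lowess_curve(x, y, frac = 0.5, iters = 3)
  interior <- f$x > 0.1 & f$x < 0.9
  expect_lt(max(abs(f$y[interior] - 2 * f$x[interior])), 0.05)

  y_out <- y; y_out[100] <- 50
  f_out <- lowess_curve(x, y_out, frac = 0.5, iters = 3)
  expect_lt(max(abs(f$y - f_out$y)), 0.05)

  expect_error(lowess_curve(x[1:5], y[1:5]), "at least 10")
})

test_that("SD-versus-intensity points are per gene and condition", {
  v <- rbind(g1 = c(1, 1, 1, 1, 1, 7, 7, 7, 7, 7),
             g2 = c(1, 2, 3, 4, 5, 2, 2, 2, 2, 2))
  m <- gene_matrix(v, rep(c("A", "B"), each = 5))
  # replicate more genes so the smoother has enough points
  v_big <- v[rep(1:2, 10), ]
  rownames(v_big) <- sprintf("g%02d", 1:20)
  m_big <- gene_matrix(v_big, rep(c("A", "B"), each = 5))
  sc <- sd_vs_intensity(m_big)
  pts <- sc$points
  expect_equal(nrow(pts), 40)    # 20 genes x 2 conditions
  expect_equal(pts$sd[pts$gene_id == "g01" & pts$condition == "A"], 0)
  expect_equal(pts$sd[pts$gene_id == "g02" & pts$condition == "A"],
               sqrt(2.5))
})

test_that("concordance separates linearity from agreement", {
  set.seed(32)
  a <- stats::rnorm(500, 2, 1.3)
  same <- concordance(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$icc, 1)

  half <- concordance(a, 0.5 * a)
  expect_equal(half$pearson_r, 1)
  expect_lt(half$icc, 1)

  # Pearson r invariant under positive affine rescaling; ICC is not
  shifted <- concordance(a, 2 * a + 1)
  expect_equal(shifted$pearson_r, 1)
  expect_lt(shifted$icc, 1)

  set.seed(33)
  x <- stats::rnorm(10000); y <- stats::rnorm(10000)
  indep <- concordance(x, y)
  expect_lt(abs(indep$pearson_r), 0.05)
  expect_lt(abs(indep$icc), 0.05)

  expect_error(concordance(rep(1, 10), stats::rnorm(10)), "zero variance")
  expect_error(concordance(1:2, 2:1), "at least 3")
})

test_that("p-value concordance works on the probit scale with clipping", {
  expect_equal(stats::qnorm(0.5), 0)
  p <- c(1e-320, 1e-8, 0.05, 0.5, 1)
  res <- pvalue_concordance(p, p)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$icc, 1)
  expect_true(all(is.finite(stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16)))))
})

test_that("volcano classification uses strict joint thresholds", {
  th <- volcano_thresholds()     # |logfc| > 1, p < 1e-6
  de <- data.frame(gene_id = paste0("g", 1:5),
                   logfc = c(1.5, 1.5, 1.0, -1.2, NA),
                   t_stat = 1,
                   p = c(1e-8, 1e-5, 1e-8, 1e-9, 1e-9),
                   ref_intensity = 1)
  class(de) <- c("de_result", "data.frame")
  calls <- classify_volcano(de, th)
  expect_identical(unname(calls), c(TRUE, FALSE, FALSE, TRUE, NA))
})

test_that("confusion metrics count jointly classified genes", {
  g <- c(TRUE, TRUE, FALSE, FALSE, NA, TRUE)
  p <- c(TRUE, FALSE, TRUE, FALSE, TRUE, NA)
  ct <- confusion_metrics(g, p)
  expect_equal(c(ct$tp, ct$fn, ct$fp, ct$tn), c(1, 1, 1, 1))
  expect_equal(ct$n, 4)

  perfect <- confusion_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  # undefined metrics are flagged, never silently zero
  no_pos <- confusion_metrics(c(FALSE, FALSE), c(FALSE, TRUE))
  expect_true(is.na(no_pos$sensitivity))
  no_neg <- confusion_metrics(c(TRUE, TRUE), c(FALSE, TRUE))
  expect_true(is.na(no_neg$specificity))
})

test_that("the comparison report pools sites and covers the method grid", {
  cfg <- sim_config(n_genes = 60, n_sites = 2, n_arrays_per_condition = 2,
                    seed = 16)
  sim <- simulate_dataset(cfg)
  gold <- simulate_gold_standard(sim$truth, seed = 17)
  report <- compare_methods(sim$dataset, gold)
  methods <- paste(method_grid()$correction, method_grid()$transform,
                   sep = "+")
  expect_setequal(unique(report$concordance_fc$method), methods)
  expect_equal(nrow(report$concordance_fc), 2 * 8)
  expect_named(report$confusion,
               c("edwards+log2", "edwards+glog", "edwards+hybrid"))
  # pooling across two sites doubles the per-site point count
  per_site <- nrow(compression_per_gene(report$de$site1[["edwards+log2"]], gold))
  expect_equal(nrow(report$compression[["edwards+log2"]]$points), 2 * per_site)
  expect_true(all(vapply(report$sd_curves,
                         function(s) nrow(s$points) == 2 * 2 * 60,
                         logical(1))))
})
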