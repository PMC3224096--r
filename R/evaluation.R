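#' Per-gene reference intensity
#'
#' The common x-axis used by all compression and SD curves: for each gene,
#' the minimum over the two conditions of the mean (over all arrays and
#' replicate spots) of the log2 standard-corrected intensities, ignoring
#' missing values.  Always derived from the standard correction + log2
#' regardless of the method under evaluation, so curves for different
#' methods share an axis.  Missing when one condition has no finite value.
#'
#' @param dataset a `spot_dataset`.
#' @return named numeric vector of log2-scale reference intensities.
#' @export
reference_intensity <- function(dataset) {
  std <- correct_standard(dataset)
  lv <- ifelse(is.finite(std$values) & std$values > 0,
               suppressWarnings(log2(std$values)), NA_real_)
  genes <- row_genes(lv)
  cond <- std$design$condition[match(colnames(lv), std$design$array_id)]
  cond_mean <- function(cc) {
    sub <- lv[, cond == cc, drop = FALSE]
    ok <- !is.na(sub)
    sums <- rowsum(ifelse(ok, sub, 0), genes)
    cnt <- rowsum(ok + 0, genes)
    tot <- rowSums(sums); n <- rowSums(cnt)
    ifelse(n > 0, tot / n, NA_real_)
  }
  m_a <- cond_mean("A")
  m_b <- cond_mean("B")
  pmin(m_a, m_b)
}

#' Per-gene fold-change compression against a gold standard
#'
#' Compression = |gold log2 fold-change| - |platform log2 fold-change| for
#' every gene shared between the result and the gold standard with a finite
#' platform fold-change.  Positive values mean the platform attenuates the
#' effect size (a gold fold-change of 64, i.e. 6 log2 units, compressed by
#' 5 leaves a platform fold-change near 2); negative values mean expansion.
#'
#' @param de a `de_result` (with `ref_intensity`).
#' @param gold a `gold_standard`.
#' @return data.frame: `gene_id`, `ref_intensity`, `compression`.
#' @export
compression_per_gene <- function(de, gold) {
  m <- merge(as.data.frame(de)[, c("gene_id", "logfc", "ref_intensity")],
             as.data.frame(gold)[, c("gene_id", "logfc_gold")],
             by = "gene_id")
  m <- m[is.finite(m$logfc), ]
  if (nrow(m) == 0) {
    stop("no shared gene with finite fold-change", call. = FALSE)
  }
  data.frame(gene_id = m$gene_id, ref_intensity = m$ref_intensity,
             compression = abs(m$logfc_gold) - abs(m$logfc),
             stringsAsFactors = FALSE)
}

#' Robust locally weighted regression curve
#'
#' Locally weighted scatterplot smoothing with tricube weights over the
#' `frac * n` nearest neighbours and `iters` robustifying iterations,
#' evaluated at the sorted unique x values (delegates to [stats::lowess()]).
#'
#' @param x,y numeric vectors; at least 10 finite pairs.
#' @param frac smoother span (fraction of points in each local fit).
#' @param iters robustifying iterations.
#' @return data.frame `x`, `y` with strictly increasing `x`.
#' @export
lowess_curve <- function(x, y, frac = 0.3, iters = 3) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop("need at least 10 finite pairs", call. = FALSE)
  fit <- stats::lowess(x[ok], y[ok], f = frac, iter = iters)
  d <- data.frame(x = fit$x, y = fit$y)
  d <- stats::aggregate(y ~ x, d, mean)
  d[order(d$x), , drop = FALSE]
}

#' Compression curve for one preprocessing method
#'
#' @param de a `de_result`.
#' @param gold a `gold_standard`.
#' @param frac,iters smoother parameters for [lowess_curve()].
#' @return list of class `compression_curve`: `points` (per-gene
#'   compressions vs reference intensity), `lowess` (fitted curve),
#'   `method`.
#' @export
compression_curve <- function(de, gold, frac = 0.3, iters = 3) {
  pts <- compression_per_gene(de, gold)
  lw <- lowess_curve(pts$ref_intensity, pts$compression, frac, iters)
  structure(list(points = pts, lowess = lw,
                 method = paste(attr(de, "correction"),
                                attr(de, "transform"), sep = "+")),
            class = "compression_curve")
}

#' Replicate SD versus reference intensity
#'
#' One point per gene per condition: the standard deviation of the
#' processed gene-level values across replicate arrays, plotted against the
#' mean reference value for that gene and condition.  The reference axis is
#' the standard correction + log2 pipeline (supply its gene-level matrix as
#' `reference`; defaults to `processed` itself).
#'
#' @param processed gene-level `transformed_matrix` of the method under
#'   evaluation.
#' @param reference gene-level `transformed_matrix` providing the x-axis;
#'   `NULL` uses `processed`.
#' @param frac,iters smoother parameters.
#' @return list of class `sd_curve`: `points` (`gene_id`, `condition`,
#'   `mean_ref`, `sd`), `lowess`.
#' @export
sd_vs_intensity <- function(processed, reference = NULL, frac = 0.3,
                            iters = 3) {
  if (is.null(reference)) reference <- processed
  v <- processed$values
  r <- reference$values
  stopifnot(identical(rownames(v), rownames(r)))
  cond <- processed$design$condition[match(colnames(v),
                                           processed$design$array_id)]
  cond_r <- reference$design$condition[match(colnames(r),
                                             reference$design$array_id)]
  pts <- do.call(rbind, lapply(c("A", "B"), function(cc) {
    sub <- v[, cond == cc, drop = FALSE]
    if (ncol(sub) < 2) stop("need >= 2 replicate arrays per condition",
                            call. = FALSE)
    rsub <- r[, cond_r == cc, drop = FALSE]
    data.frame(gene_id = rownames(v), condition = cc,
               mean_ref = rowMeans(rsub, na.rm = TRUE),
               sd = apply(sub, 1, stats::sd, na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  lw <- lowess_curve(pts$mean_ref, pts$sd, frac, iters)
  structure(list(points = pts, lowess = lw), class = "sd_curve")
}

#' Pearson and intraclass correlation between two measurements
#'
#' The product-moment correlation measures the strength of linear
#' dependence; the intraclass correlation (one-way random-effects, single
#' measure: `(MSB - MSW) / (MSB + MSW)` from the two-column table of paired
#' values) additionally penalizes location and scale disagreement, so a
#' uniform halving of one vector leaves r = 1 but lowers the ICC.
#'
#' @param a,b numeric vectors of equal length; at least 3 finite pairs.
#' @return list of class `concordance_result`: `pearson_r`, `icc`, `n`.
#' @export
concordance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance: concordance undefined", call. = FALSE)
  }
  r <- stats::cor(a, b)
  m <- (a + b) / 2
  grand <- mean(m)
  msb <- 2 * sum((m - grand)^2) / (n - 1)
  msw <- sum((a - b)^2 / 2) / n
  icc <- (msb - msw) / (msb + msw)
  structure(list(pearson_r = r, icc = icc, n = n),
            class = "concordance_result")
}

#' Concordance of p-values on the probit scale
#'
#' Applies the standard normal quantile function to both p-value vectors
#' (clipped to `[1e-300, 1 - 1e-16]` so extreme values stay finite) and
#' delegates to [concordance()].  Small p-values map to large negative
#' quantiles; the direction does not affect the magnitudes of r or ICC
#' between two p-value vectors.
#'
#' @param p_a,p_b p-value vectors in (0, 1].
#' @return a `concordance_result`.
#' @export
pvalue_concordance <- function(p_a, p_b) {
  clip <- function(p) stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16))
  concordance(clip(p_a), clip(p_b))
}

#' Volcano classification thresholds
#'
#' A gene is called differentially expressed when its absolute log2
#' fold-change is strictly higher than `fc_threshold` and its p-value is
#' strictly lower than `p_threshold` (the p cut accounts for multiple
#' testing by being fixed very low rather than adjusted).
#'
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param p_threshold p-value threshold (default 1e-6).
#' @return list of class `volcano_thresholds`.
#' @export
volcano_thresholds <- function(fc_threshold = 1, p_threshold = 1e-6) {
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold),
            class = "volcano_thresholds")
}

#' Classify genes from a volcano plot rule
#'
#' @param x a `de_result` or `gold_standard` (columns `logfc`/`p` or
#'   `logfc_gold`/`p_gold`).
#' @param thresholds a [volcano_thresholds()].
#' @return named logical vector of calls; `NA` (flagged, not called) where
#'   fold-change or p-value is missing.
#' @export
classify_volcano <- function(x, thresholds = volcano_thresholds()) {
  lfc <- if ("logfc" %in% names(x)) x$logfc else x$logfc_gold
  p <- if ("p" %in% names(x)) x$p else x$p_gold
  call <- abs(lfc) > thresholds$fc_threshold & p < thresholds$p_threshold
  call[!is.finite(lfc) | !is.finite(p)] <- NA
  names(call) <- x$gene_id
  call
}

#' Confusion table and derived classification metrics
#'
#' Cross-tabulates gold-standard calls against platform calls over the
#' genes classified by both.  Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/total; a metric whose denominator is zero
#' is reported as `NA` rather than silently 0.
#'
#' @param calls_gold,calls_platform logical vectors over the same gene set
#'   (`NA` = unclassified; pairs with any `NA` are dropped).
#' @return list of class `confusion_table`: `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `n`.
#' @export
confusion_metrics <- function(calls_gold, calls_platform) {
  stopifnot(length(calls_gold) == length(calls_platform))
  ok <- !is.na(calls_gold) & !is.na(calls_platform)
  g <- calls_gold[ok]; p <- calls_platform[ok]
  tp <- sum(g & p); tn <- sum(!g & !p)
  fp <- sum(!g & p); fn <- sum(g & !p)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 n = tp + tn + fp + fn),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n))
  cat(sprintf("sensitivity=%.3f specificity=%.3f accuracy=%.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("r=%.3f ICC=%.3f (n=%d)\n", x$pearson_r, x$icc, x$n))
  invisible(x)
}
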