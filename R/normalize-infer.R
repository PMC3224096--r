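#' Global median normalization
#'
#' Per array, subtracts the array median of the finite transformed values
#' and adds back the grand median (the median of the per-array medians), so
#' all arrays end up with equal medians while within-array differences are
#' untouched.  Idempotent.
#'
#' @param tm a `transformed_matrix`; every array must have at least one
#'   finite value.
#' @return the normalized `transformed_matrix`.
#' @export
global_median_normalize <- function(tm) {
  v <- tm$values
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) {
    stop(sprintf("array %s has no finite value",
                 colnames(v)[which(!is.finite(med))[1]]), call. = FALSE)
  }
  grand <- stats::median(med)
  tm$values <- sweep(v, 2, med - grand)
  tm
}

#' Average replicate spots to gene level
#'
#' Per gene per array, the mean of the non-missing replicate-spot values;
#' missing only when all of a gene's spots are missing on that array.
#'
#' @param tm a spot-level `transformed_matrix` (rows `gene#replicate`).
#' @return a gene-level matrix object of the same class (rows = genes).
#' @export
average_replicate_spots <- function(tm) {
  v <- tm$values
  genes <- row_genes(v)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  sums <- rowsum(v0, genes)
  cnt <- rowsum(ok + 0, genes)
  out <- ifelse(cnt > 0, sums / cnt, NA_real_)
  tm$values <- out
  tm
}

#' Per-gene two-group linear model fits
#'
#' For each gene with at least two finite values in each condition, the
#' log2 fold-change `mean(B) - mean(A)`, the pooled residual variance
#' `s_g^2`, the residual degrees of freedom `d_g = n_finite - 2` and the
#' unscaled variance factor `v = 1/n_A + 1/n_B`.  Genes failing the
#' requirement get missing results.
#'
#' @param tm a gene-level `transformed_matrix`.
#' @param design optional condition labels per array; defaults to the
#'   design stored in `tm`.
#' @return data.frame of class `lm_fits`: `gene_id`, `logfc`, `s2`, `df`,
#'   `v`, `n_A`, `n_B`.
#' @export
fit_linear_model <- function(tm, design = NULL) {
  v <- tm$values
  cond <- if (is.null(design)) {
    tm$design$condition[match(colnames(v), tm$design$array_id)]
  } else {
    design
  }
  stopifnot(length(cond) == ncol(v), all(cond %in% c("A", "B")))
  a <- v[, cond == "A", drop = FALSE]
  b <- v[, cond == "B", drop = FALSE]
  n_a <- rowSums(is.finite(a))
  n_b <- rowSums(is.finite(b))
  fit_ok <- n_a >= 2 & n_b >= 2
  if (!any(fit_ok)) stop("no gene has >= 2 finite values per condition",
                         call. = FALSE)
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  ss <- rowSums((a - mean_a)^2, na.rm = TRUE) +
    rowSums((b - mean_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2
  out <- data.frame(
    gene_id = rownames(v),
    logfc = ifelse(fit_ok, mean_b - mean_a, NA_real_),
    s2 = ifelse(fit_ok, ss / df, NA_real_),
    df = ifelse(fit_ok, df, NA_real_),
    v = ifelse(fit_ok, 1 / n_a + 1 / n_b, NA_real_),
    n_A = n_a, n_B = n_b,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("lm_fits", "data.frame")
  out
}

#' Empirical-Bayes prior for gene-wise variances
#'
#' @param d0 prior degrees of freedom (> 0; may be `Inf`).  `d0 = 0` is
#'   accepted as the no-moderation limit.
#' @param s0_sq prior variance (> 0).
#' @return list of class `ebayes_prior`.
#' @export
ebayes_prior <- function(d0, s0_sq) {
  if (d0 < 0) stop("d0 must be >= 0", call. = FALSE)
  if (!is.finite(s0_sq) || s0_sq <= 0) stop("s0_sq must be > 0", call. = FALSE)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

## Newton inversion of the trigamma function: solve trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

## moment estimation of (d0, s0_sq): ln s^2 given sigma^2 is
## ln(sigma^2 chi^2_d / d); under the scaled-F prior predictive the
## digamma/trigamma identities give closed-form moment equations.
estimate_ebayes_prior <- function(s2, df) {
  keep <- is.finite(s2) & is.finite(df) & df >= 1 & s2 > 0
  if (sum(keep) < 10) {
    stop("need at least 10 genes with positive residual variance",
         call. = FALSE)
  }
  s2 <- s2[keep]; df <- df[keep]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  ebayes_prior(d0, s0_sq)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks each gene's residual variance toward a prior estimated across
#' genes by matching the first two moments of `ln s_g^2` to the scaled-F
#' prior predictive (digamma/trigamma moment equations with Newton
#' inversion of the trigamma function).  The posterior variance is
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, the moderated t is
#' `logfc / (s~_g sqrt(v))` and the two-sided p-value uses `d0 + d_g`
#' degrees of freedom.  With `d0 = 0` this reduces exactly to the classical
#' pooled two-sample t-test; with `d0 = Inf` every variance equals `s0^2`.
#'
#' @param fits an `lm_fits` from [fit_linear_model()].
#' @param prior optional [ebayes_prior()]; estimated from `fits` when `NULL`.
#' @param ref_intensity optional per-gene log2 reference intensity, named by
#'   gene id, carried through to the result.
#' @return data.frame of class `de_result`: `gene_id`, `logfc`, `t_stat`,
#'   `p`, `ref_intensity`; attributes `prior`, `correction`, `transform`.
#' @export
ebayes_moderate <- function(fits, prior = NULL, ref_intensity = NULL) {
  if (is.null(prior)) {
    if (all(!is.finite(fits$s2) | fits$s2 == 0)) {
      stop("all residual variances are zero; cannot estimate prior",
           call. = FALSE)
    }
    prior <- estimate_ebayes_prior(fits$s2, fits$df)
  }
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) {
    ifelse(is.finite(fits$s2), s0, NA_real_)
  } else if (d0 == 0) {
    fits$s2
  } else {
    (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df)
  }
  df_total <- if (is.infinite(d0)) Inf else d0 + fits$df
  t_stat <- fits$logfc / sqrt(s2_post * fits$v)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p <- pmax(p, .Machine$double.xmin)
  ref <- if (is.null(ref_intensity)) {
    NA_real_
  } else {
    unname(ref_intensity[fits$gene_id])
  }
  out <- data.frame(gene_id = fits$gene_id, logfc = fits$logfc,
                    t_stat = t_stat, p = p, ref_intensity = ref,
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  class(out) <- c("de_result", "data.frame")
  out
}

#' Run a full preprocessing and inference pipeline
#'
#' Executes background correction, transformation, global-median
#' normalization, replicate-spot averaging, per-gene linear-model fitting
#' and empirical-Bayes moderation, and attaches the per-gene reference
#' intensity (minimum condition mean after standard correction + log2; see
#' [reference_intensity()]).  `transform = "hybrid"` runs both transforms
#' and combines them with [hybrid_combine()]: fold-changes from log2,
#' p-values from glog.
#'
#' @param dataset a `spot_dataset`.
#' @param correction `"standard"`, `"none"`, `"edwards"` or `"normexp"`.
#' @param transform `"log2"`, `"glog"` or `"hybrid"`.
#' @param edwards_delta optional Edwards threshold.
#' @param glog_parameters optional [glog_params()]; estimated from the
#'   corrected matrix when `NULL`.
#' @param prior optional [ebayes_prior()].
#' @return a `de_result` with attributes `correction`, `transform`,
#'   `params`.
#' @export
run_pipeline <- function(dataset,
                         correction = c("standard", "none", "edwards",
                                        "normexp"),
                         transform = c("log2", "glog", "hybrid"),
                         edwards_delta = NULL, glog_parameters = NULL,
                         prior = NULL) {
  correction <- match.arg(correction)
  transform <- match.arg(transform)
  if (transform == "hybrid") {
    corrected <- correct_background(dataset, correction, edwards_delta)
    de_log2 <- run_pipeline_corrected(dataset, corrected, "log2", NULL, prior)
    de_glog <- run_pipeline_corrected(dataset, corrected, "glog",
                                      glog_parameters, prior)
    return(hybrid_combine(de_log2, de_glog))
  }
  corrected <- correct_background(dataset, correction, edwards_delta)
  run_pipeline_corrected(dataset, corrected, transform, glog_parameters,
                         prior)
}

run_pipeline_corrected <- function(dataset, corrected, transform,
                                   glog_parameters, prior) {
  tm <- if (transform == "log2") {
    log2_transform(corrected)
  } else {
    glog_transform(corrected, glog_parameters)
  }
  tm <- global_median_normalize(tm)
  gene_tm <- average_replicate_spots(tm)
  fits <- fit_linear_model(gene_tm)
  ref <- reference_intensity(dataset)
  de <- ebayes_moderate(fits, prior, ref_intensity = ref)
  attr(de, "correction") <- corrected$method
  attr(de, "transform") <- transform
  attr(de, "params") <- list(correction = corrected$params,
                             glog = tm$glog_params)
  de
}

#' Combine log2 and glog pipeline results into the hybrid method
#'
#' The hybrid transformation keeps the fold-change magnitudes of the log2
#' pipeline (which compresses fold-changes least) and the p-values of the
#' glog pipeline (whose stabilized variance yields better-calibrated
#' significance), for the same background correction.
#'
#' @param de_log2 `de_result` from a log2 pipeline.
#' @param de_glog `de_result` from a glog pipeline with the same correction.
#' @return a `de_result` with `transform = "hybrid"`: `logfc` and
#'   `ref_intensity` from `de_log2`, `t_stat` and `p` from `de_glog`.
#' @export
hybrid_combine <- function(de_log2, de_glog) {
  if (!identical(de_log2$gene_id, de_glog$gene_id)) {
    stop("gene sets of the two results differ", call. = FALSE)
  }
  c1 <- attr(de_log2, "correction"); c2 <- attr(de_glog, "correction")
  if (!is.null(c1) && !is.null(c2) && !identical(c1, c2)) {
    stop(sprintf("background corrections differ: %s vs %s", c1, c2),
         call. = FALSE)
  }
  out <- de_log2
  out$t_stat <- de_glog$t_stat
  out$p <- de_glog$p
  attr(out, "transform") <- "hybrid"
  attr(out, "params") <- list(log2 = attr(de_log2, "params"),
                              glog = attr(de_glog, "params"))
  out
}

#' Write a differential-expression result table
#'
#' TSV with columns `gene_id`, `logfc` (log2 fold-change, condition B over
#' condition A), `t_stat`, `p`, `ref_intensity`.
#'
#' @param de a `de_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a differential-expression result table
#'
#' @param path input path.
#' @return a `de_result` data.frame.
#' @export
read_de_result <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(gene_id = "character"))
  class(de) <- c("de_result", "data.frame")
  de
}
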