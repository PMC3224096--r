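#' OLS slope of foreground on local background over replicate spots
#'
#' For the replicate spots of one gene on one array, the ordinary
#' least-squares slope of the foreground intensity on the local background
#' intensity.  If the specific hybridization is roughly constant across the
#' replicate spots, differences among their foregrounds are driven by the
#' background, and the slope should be close to 1 when background noise
#' acts additively on the foreground.
#'
#' @param F_triplet,B_triplet numeric vectors of equal length (>= 2).
#' @return the slope, or `NA` when all background values are equal
#'   (degenerate triplet).
#' @export
per_spot_regression <- function(F_triplet, B_triplet) {
  stopifnot(length(F_triplet) == length(B_triplet),
            length(F_triplet) >= 2)
  ssb <- sum((B_triplet - mean(B_triplet))^2)
  if (ssb == 0) return(NA_real_)
  sum((B_triplet - mean(B_triplet)) * (F_triplet - mean(F_triplet))) / ssb
}

#' Trimmed-mean slope with confidence interval
#'
#' Symmetric trimming: `trim_fraction` of the slopes in total
#' (`trim_fraction/2` from each tail of the sorted slopes), then the mean
#' of what remains.  The 95% interval is `trimmed mean +/- 1.96 * SE` with
#' the standard error of a trimmed mean from the winsorized variance,
#' `SE = s_w / ((1 - trim_fraction) * sqrt(n))`.  A seeded bootstrap
#' interval is available as a sensitivity check.
#'
#' @param slopes numeric vector (non-finite entries are dropped and
#'   counted); at least 20 finite slopes.
#' @param trim_fraction total fraction trimmed, in `[0, 0.5)`.
#' @param ci_method `"winsorized"` (default) or `"bootstrap"`.
#' @param boot_n,boot_seed bootstrap resamples and seed.
#' @return list of class `additivity_result`: `slopes`, `n_excluded`,
#'   `trimmed_mean`, `ci_low`, `ci_high`, `trim_fraction`.
#' @export
trimmed_mean_slope <- function(slopes, trim_fraction = 0.05,
                               ci_method = c("winsorized", "bootstrap"),
                               boot_n = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  n_excluded <- sum(!is.finite(slopes))
  s <- slopes[is.finite(slopes)]
  if (length(s) < 20) stop("need at least 20 finite slopes", call. = FALSE)
  tm_ci <- function(s) {
    n <- length(s)
    g <- floor(n * trim_fraction / 2)
    srt <- sort(s)
    kept <- if (g > 0) srt[(g + 1):(n - g)] else srt
    tm <- mean(kept)
    ## winsorized sample: tails replaced by the nearest kept value
    wins <- c(rep(kept[1], g), kept, rep(kept[length(kept)], g))
    sw <- stats::sd(wins)
    se <- sw / ((1 - 2 * g / n) * sqrt(n))
    c(tm, tm - 1.96 * se, tm + 1.96 * se)
  }
  est <- tm_ci(s)
  if (ci_method == "bootstrap") {
    set.seed(boot_seed)
    bt <- replicate(boot_n, tm_ci(sample(s, replace = TRUE))[1])
    ci <- stats::quantile(bt, c(0.025, 0.975), names = FALSE)
    est[2:3] <- ci
  }
  structure(list(slopes = slopes, n_excluded = n_excluded,
                 trimmed_mean = est[1], ci_low = est[2], ci_high = est[3],
                 trim_fraction = trim_fraction),
            class = "additivity_result")
}

#' Test the additive-background hypothesis on a dataset
#'
#' Computes one foreground-on-background OLS slope per gene per array from
#' the replicate spots, then the trimmed-mean slope and its 95% interval.
#' Under exactly additive background noise the slopes concentrate around 1
#' and the interval covers 1; background that does not propagate into the
#' foreground yields slopes around 0.
#'
#' @param dataset a `spot_dataset` with at least 2 replicate spots per gene.
#' @param trim_fraction,ci_method,boot_n,boot_seed forwarded to
#'   [trimmed_mean_slope()].
#' @return an `additivity_result`, with the extra element `contains_one`.
#' @export
run_additivity_test <- function(dataset, trim_fraction = 0.05,
                                ci_method = c("winsorized", "bootstrap"),
                                boot_n = 2000, boot_seed = 1L) {
  if (dataset$n_spot_replicates < 2) {
    stop("need at least 2 replicate spots per gene", call. = FALSE)
  }
  F <- spot_matrix(dataset, "F")
  B <- spot_matrix(dataset, "B")
  genes <- row_genes(F)
  gene_ids <- unique(genes)
  slopes <- numeric(0)
  for (a in colnames(F)) {
    fa <- F[, a]; ba <- B[, a]
    ssb_mean <- rowsum(ba, genes) / as.vector(rowsum(rep(1, length(ba)), genes))
    bc <- ba - ssb_mean[match(genes, rownames(ssb_mean)), 1]
    fc_mean <- rowsum(fa, genes) / as.vector(rowsum(rep(1, length(fa)), genes))
    fcv <- fa - fc_mean[match(genes, rownames(fc_mean)), 1]
    ssb <- rowsum(bc^2, genes)
    sxy <- rowsum(bc * fcv, genes)
    sl <- ifelse(ssb[, 1] > 0, sxy[, 1] / ssb[, 1], NA_real_)
    slopes <- c(slopes, sl)
  }
  res <- trimmed_mean_slope(slopes, trim_fraction, ci_method, boot_n,
                            boot_seed)
  res$contains_one <- res$ci_low <= 1 && 1 <= res$ci_high
  res
}

#' Spatial grid of local background intensities for one array
#'
#' @param dataset a `spot_dataset`.
#' @param array_id which array.
#' @return numeric matrix indexed by grid row and column (`NA` at unspotted
#'   positions), suitable for heatmap rendering and for
#'   [neighbour_correlation()].
#' @export
spatial_background_grid <- function(dataset, array_id) {
  sp <- dataset$spots[dataset$spots$array_id == array_id, ]
  if (nrow(sp) == 0) stop(sprintf("unknown array_id %s", array_id),
                          call. = FALSE)
  if (anyDuplicated(paste(sp$grid_row, sp$grid_col))) {
    stop("duplicate grid coordinates on array", call. = FALSE)
  }
  nr <- max(sp$grid_row) + 1
  nc <- max(sp$grid_col) + 1
  g <- matrix(NA_real_, nr, nc)
  g[cbind(sp$grid_row + 1, sp$grid_col + 1)] <- sp$B
  g
}

#' Mean correlation of background between grid-adjacent spots
#'
#' Pools horizontally and vertically adjacent pairs of spotted positions
#' and returns their Pearson correlation.  Spatially structured background
#' gives a clearly positive value; spatially unstructured background gives
#' a value near 0.
#'
#' @param grid matrix from [spatial_background_grid()].
#' @return correlation coefficient.
#' @export
neighbour_correlation <- function(grid) {
  h1 <- as.vector(grid[, -ncol(grid)]); h2 <- as.vector(grid[, -1])
  v1 <- as.vector(grid[-nrow(grid), ]); v2 <- as.vector(grid[-1, ])
  a <- c(h1, v1); b <- c(h2, v2)
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok])
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("trimmed-mean slope %.3f, 95%% CI (%.3f; %.3f), trim %.1f%%, %d slopes (%d excluded)\n",
              x$trimmed_mean, x$ci_low, x$ci_high, 100 * x$trim_fraction,
              sum(is.finite(x$slopes)), x$n_excluded))
  invisible(x)
}
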