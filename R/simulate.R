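#' Simulation configuration for synthetic spotted-array data
#'
#' The generator emulates the structure that drives preprocessing behaviour
#' on real one-color spotted arrays: a spatially structured additive
#' background under every spot, a two-component (multiplicative +
#' additive) measurement error on the specific signal, replicate spots per
#' gene, replicate arrays in two conditions at two sites, a mixture of null
#' and differentially expressed genes, and a matched low-noise gold
#' standard.  Per spot the generative rule is
#' `F = background_slope * B + mu * exp(eta) + eps`, with `B` the true local
#' background at the spot's grid position, `eta ~ N(0, eta_sd^2)` and
#' `eps ~ N(0, eps_sd^2)`; `F` is truncated at 0 (by resampling `eps`, then
#' clipping) and the observed local background equals `B`.
#'
#' Defaults describe a low-density triplicate-spotted cDNA array: 1000
#' genes, 5 arrays per condition per site, two sites, baseline expression
#' log-normal around 2^7 AFU with spread 1.8 log2 units, background around
#' 150 AFU with a smooth spatial trend (SD 40) plus per-spot noise (SD 20),
#' multiplicative error SD 0.25 on the natural-log scale and additive error
#' SD 50 AFU.  Under these settings a non-trivial fraction of spots (about
#' one in ten) has foreground below local background, so standard
#' subtraction produces negative corrected intensities and the log2
#' pipeline produces missing values, as on real data.
#'
#' @param n_genes number of genes.
#' @param n_arrays_per_condition replicate arrays per condition per site.
#' @param n_sites number of sites (independent datasets sharing the truth).
#' @param n_spot_replicates replicate spots per gene per array.
#' @param grid_shape integer `(rows, cols)`; must hold
#'   `n_genes * n_spot_replicates` spots.  Default: smallest square that fits.
#' @param background_mean,background_spatial_sd,background_spot_sd AFU; mean
#'   of the background field, SD of its smooth spatial trend, SD of
#'   independent per-spot background noise.
#' @param baseline_log2_mean,baseline_log2_sd log2-AFU; per-gene baseline
#'   expression in condition A is `2^N(baseline_log2_mean, baseline_log2_sd^2)`.
#' @param prop_de fraction of genes differentially expressed.
#' @param logfc_range `(lo, hi)`: true |log2 fold-change| of DE genes is
#'   uniform on this range, with random sign.
#' @param eta_sd SD of the multiplicative log-normal error (natural-log scale).
#' @param eps_sd AFU; SD of the additive error.
#' @param background_slope effect of local background on foreground
#'   (1 = exactly additive background noise).
#' @param gold_noise_sd log2 units; replicate noise of the gold standard.
#' @param gold_n_replicates gold-standard replicates per condition.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_arrays_per_condition = 5,
                       n_sites = 2,
                       n_spot_replicates = 3,
                       grid_shape = NULL,
                       background_mean = 150,
                       background_spatial_sd = 40,
                       background_spot_sd = 20,
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 1.8,
                       prop_de = 0.3,
                       logfc_range = c(0.5, 6),
                       eta_sd = 0.25,
                       eps_sd = 50,
                       background_slope = 1,
                       gold_noise_sd = 0.2,
                       gold_n_replicates = 4,
                       seed = 1L) {
  if (is.null(grid_shape)) {
    side <- ceiling(sqrt(n_genes * n_spot_replicates))
    grid_shape <- c(side, side)
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_arrays_per_condition = as.integer(n_arrays_per_condition),
              n_sites = as.integer(n_sites),
              n_spot_replicates = as.integer(n_spot_replicates),
              grid_shape = as.integer(grid_shape),
              background_mean = background_mean,
              background_spatial_sd = background_spatial_sd,
              background_spot_sd = background_spot_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              prop_de = prop_de,
              logfc_range = logfc_range,
              eta_sd = eta_sd,
              eps_sd = eps_sd,
              background_slope = background_slope,
              gold_noise_sd = gold_noise_sd,
              gold_n_replicates = as.integer(gold_n_replicates),
              seed = as.integer(seed))
  if (prod(cfg$grid_shape) < cfg$n_genes * cfg$n_spot_replicates) {
    stop("grid too small: needs at least n_genes * n_spot_replicates cells",
         call. = FALSE)
  }
  sds <- c(cfg$background_spatial_sd, cfg$background_spot_sd,
           cfg$baseline_log2_sd, cfg$eta_sd, cfg$eps_sd, cfg$gold_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$prop_de < 0 || cfg$prop_de > 1) stop("prop_de must lie in [0, 1]",
                                               call. = FALSE)
  if (cfg$background_mean <= 0) stop("background_mean must be positive",
                                     call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

## derive a sub-seed from a master seed and a stage counter, kept within
## 32-bit integer range
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * counter) %% .Machine$integer.max)
}

#' Simulate a spatially structured background field
#'
#' A smooth low-frequency surface (sum of three cosine modes per axis with
#' seeded random amplitudes and phases, rescaled to SD
#' `background_spatial_sd` over the grid) plus independent per-cell Gaussian
#' noise with SD `background_spot_sd`, shifted to `background_mean` and
#' clipped at 0.  This mimics local background intensities that depend on
#' spatial position rather than on the spot's own foreground.
#'
#' @param grid_shape integer `(rows, cols)`, both >= 1.
#' @param background_mean mean background (AFU, > 0).
#' @param background_spatial_sd SD of the smooth trend (AFU).
#' @param background_spot_sd SD of per-cell noise (AFU).
#' @param seed integer seed.
#' @return numeric `rows x cols` matrix of background values (AFU, >= 0).
#' @export
simulate_background_field <- function(grid_shape, background_mean,
                                      background_spatial_sd,
                                      background_spot_sd, seed) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            background_mean > 0, background_spatial_sd >= 0,
            background_spot_sd >= 0)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  set.seed(seed)
  surface <- matrix(0, nr, nc)
  if (background_spatial_sd > 0) {
    r <- seq_len(nr) / nr
    co <- seq_len(nc) / nc
    for (k in 1:3) {
      a_r <- stats::rnorm(1); ph_r <- stats::runif(1, 0, 2 * pi)
      a_c <- stats::rnorm(1); ph_c <- stats::runif(1, 0, 2 * pi)
      surface <- surface +
        outer(a_r * cos(2 * pi * k * r + ph_r), rep(1, nc)) +
        outer(rep(1, nr), a_c * cos(2 * pi * k * co + ph_c))
    }
    s <- stats::sd(as.vector(surface))
    if (s > 0) surface <- surface * (background_spatial_sd / s)
    surface <- surface - mean(surface)
  }
  noise <- if (background_spot_sd > 0) {
    matrix(stats::rnorm(nr * nc, 0, background_spot_sd), nr, nc)
  } else {
    0
  }
  pmax(background_mean + surface + noise, 0)
}

#' Simulate per-gene truth
#'
#' @keywords internal
simulate_truth <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1))
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
  mu_A <- 2^stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                         cfg$baseline_log2_sd)
  n_de <- round(cfg$prop_de * cfg$n_genes)
  is_de <- rep(FALSE, cfg$n_genes)
  if (n_de > 0) is_de[sample.int(cfg$n_genes, n_de)] <- TRUE
  true_logfc <- rep(0, cfg$n_genes)
  true_logfc[is_de] <- stats::runif(n_de, cfg$logfc_range[1],
                                    cfg$logfc_range[2]) *
    sample(c(-1, 1), n_de, replace = TRUE)
  mu_B <- mu_A * 2^true_logfc
  data.frame(gene_id = gene_id, true_logfc = true_logfc, is_de = is_de,
             mu_A = mu_A, mu_B = mu_B, stringsAsFactors = FALSE)
}

#' Simulate a spotted-array dataset with known truth
#'
#' Generates spot tables for `n_sites` sites, each with
#' `n_arrays_per_condition` arrays per condition (A and B).  All sites share
#' the same per-gene truth; each site has its own spot layout and each array
#' its own background field (the spatial trend varies array to array, as
#' wash and scan artifacts do).  Within an array, the replicate spots of a
#' gene share the true expression level but have independent multiplicative
#' and additive errors and distinct grid positions.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a `spot_dataset`) and `truth`
#'   (data.frame: `gene_id`, `true_logfc`, `is_de`, `mu_A`, `mu_B`).
#' @export
simulate_dataset <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  truth <- simulate_truth(cfg)
  n_cells <- prod(cfg$grid_shape)
  n_spots <- cfg$n_genes * cfg$n_spot_replicates
  counter <- 10
  all_spots <- vector("list", cfg$n_sites * 2 * cfg$n_arrays_per_condition)
  i <- 0
  for (s in seq_len(cfg$n_sites)) {
    site <- sprintf("site%d", s)
    ## fixed print layout per site: genes x replicates assigned to grid cells
    set.seed(derive_seed(cfg$seed, counter)); counter <- counter + 1
    cells <- sample.int(n_cells, n_spots)
    grid_row <- (cells - 1) %/% cfg$grid_shape[2]
    grid_col <- (cells - 1) %% cfg$grid_shape[2]
    gene_id <- rep(truth$gene_id, each = cfg$n_spot_replicates)
    spot_rep <- rep(seq_len(cfg$n_spot_replicates), times = cfg$n_genes)
    for (cond in c("A", "B")) {
      mu <- rep(if (cond == "A") truth$mu_A else truth$mu_B,
                each = cfg$n_spot_replicates)
      for (a in seq_len(cfg$n_arrays_per_condition)) {
        field <- simulate_background_field(
          cfg$grid_shape, cfg$background_mean,
          cfg$background_spatial_sd, cfg$background_spot_sd,
          seed = derive_seed(cfg$seed, counter))
        counter <- counter + 1
        B <- field[cbind(grid_row + 1, grid_col + 1)]
        set.seed(derive_seed(cfg$seed, counter)); counter <- counter + 1
        eta <- stats::rnorm(n_spots, 0, cfg$eta_sd)
        eps <- stats::rnorm(n_spots, 0, cfg$eps_sd)
        signal <- mu * exp(eta)
        F <- cfg$background_slope * B + signal + eps
        ## truncate at 0 by resampling the additive error, then clipping
        for (tries in seq_len(100)) {
          bad <- which(F < 0)
          if (length(bad) == 0) break
          eps[bad] <- stats::rnorm(length(bad), 0, cfg$eps_sd)
          F[bad] <- cfg$background_slope * B[bad] + signal[bad] + eps[bad]
        }
        F <- pmax(F, 0)
        i <- i + 1
        all_spots[[i]] <- data.frame(
          gene_id = gene_id, site = site, condition = cond,
          array_id = sprintf("%s_%s%d", site, cond, a),
          spot_replicate = spot_rep, grid_row = grid_row, grid_col = grid_col,
          F = F, B = B, stringsAsFactors = FALSE)
      }
    }
  }
  dataset <- spot_dataset(do.call(rbind, all_spots), cfg$n_spot_replicates)
  list(dataset = dataset, truth = truth)
}

#' Simulate a qPCR-like gold standard from known truth
#'
#' Per gene and condition, `gold_n_replicates` log2-scale measurements are
#' drawn as true log2 level + `N(0, gold_noise_sd^2)`; the gold fold-change
#' is the difference of condition means (B minus A) and the gold p-value
#' comes from the same linear-model machinery used for the arrays: per-gene
#' two-group fits followed by empirical-Bayes variance moderation
#' ([ebayes_moderate()]), mirroring how a qPCR reference panel is analysed
#' alongside the microarrays.  Set `moderate = FALSE` for plain two-sample
#' t-test p-values.  With `gold_noise_sd = 0` the fold-change equals the
#' truth exactly and the p-value degenerates to 1 for null genes and the
#' smallest representable positive double otherwise.
#'
#' @param truth truth data.frame from [simulate_dataset()].
#' @param gold_noise_sd replicate noise SD in log2 units (>= 0).
#' @param gold_n_replicates replicates per condition (>= 2).
#' @param seed integer seed.
#' @param moderate moderate the gold variances across genes (default);
#'   `FALSE` gives classical two-sample t-test p-values.
#' @return a `gold_standard` data.frame.
#' @export
simulate_gold_standard <- function(truth, gold_noise_sd = 0.2,
                                   gold_n_replicates = 4, seed = 1L,
                                   moderate = TRUE) {
  stopifnot(gold_noise_sd >= 0, gold_n_replicates >= 2)
  set.seed(seed)
  n <- nrow(truth)
  k <- gold_n_replicates
  a <- matrix(log2(truth$mu_A), n, k) +
    matrix(stats::rnorm(n * k, 0, gold_noise_sd), n, k)
  b <- matrix(log2(truth$mu_B), n, k) +
    matrix(stats::rnorm(n * k, 0, gold_noise_sd), n, k)
  logfc <- rowMeans(b) - rowMeans(a)
  if (gold_noise_sd == 0) {
    p <- ifelse(logfc == 0, 1, .Machine$double.xmin)
  } else {
    s2 <- (apply(a, 1, stats::var) * (k - 1) +
             apply(b, 1, stats::var) * (k - 1)) / (2 * k - 2)
    fits <- data.frame(gene_id = truth$gene_id, logfc = logfc, s2 = s2,
                       df = 2 * k - 2, v = 2 / k, stringsAsFactors = FALSE)
    class(fits) <- c("lm_fits", "data.frame")
    if (moderate) {
      p <- ebayes_moderate(fits)$p
    } else {
      tt <- logfc / sqrt(s2 * 2 / k)
      p <- pmax(2 * stats::pt(-abs(tt), df = 2 * k - 2),
                .Machine$double.xmin)
    }
  }
  gold_standard(data.frame(gene_id = truth$gene_id, logfc_gold = logfc,
                           p_gold = p, stringsAsFactors = FALSE))
}
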