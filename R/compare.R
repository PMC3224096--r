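#' Preprocessing method grid
#'
#' The eight combinations of four background corrections with two
#' transformations.
#'
#' @return data.frame with columns `correction`, `transform`.
#' @export
method_grid <- function() {
  expand.grid(correction = c("standard", "none", "edwards", "normexp"),
              transform = c("log2", "glog"),
              stringsAsFactors = FALSE)
}

## split a multi-site dataset into one spot_dataset per site
split_by_site <- function(dataset) {
  sites <- unique(dataset$spots$site)
  out <- lapply(sites, function(s) {
    spot_dataset(dataset$spots[dataset$spots$site == s, , drop = FALSE],
                 dataset$n_spot_replicates)
  })
  names(out) <- sites
  out
}

#' Compare preprocessing methods against a gold standard
#'
#' Runs every correction-by-transform pipeline on each site of the dataset
#' and assembles the full comparison report: per-site Pearson/ICC
#' concordance of fold-changes with the gold standard and of probit-scale
#' p-values, fold-change compression curves and replicate-SD curves with
#' genes pooled across sites, and volcano confusion tables for the log2,
#' glog and hybrid transforms under one chosen correction.
#'
#' @param dataset a `spot_dataset`, possibly spanning several sites.
#' @param gold a `gold_standard`.
#' @param confusion_correction background correction used for the
#'   confusion-table comparison of the three transforms.
#' @param thresholds a [volcano_thresholds()].
#' @param frac,iters smoother parameters for the curves.
#' @return list of class `preproc_report` with elements `concordance_fc`,
#'   `concordance_p` (data.frames), `compression` (named list of
#'   `compression_curve`), `sd_curves` (named list of `sd_curve`),
#'   `confusion` (named list of `confusion_table`), `de` (named list of
#'   per-site `de_result` lists), `thresholds`.
#' @export
compare_methods <- function(dataset, gold,
                            confusion_correction = "edwards",
                            thresholds = volcano_thresholds(),
                            frac = 0.3, iters = 3) {
  sites <- split_by_site(dataset)
  grid <- method_grid()
  methods <- paste(grid$correction, grid$transform, sep = "+")

  de <- lapply(sites, function(ds) {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      run_pipeline(ds, grid$correction[i], grid$transform[i])
    })
    names(res) <- methods
    ## hybrid for the confusion correction, reusing both runs
    res[[paste0(confusion_correction, "+hybrid")]] <-
      hybrid_combine(res[[paste0(confusion_correction, "+log2")]],
                     res[[paste0(confusion_correction, "+glog")]])
    res
  })

  conc_fc <- do.call(rbind, lapply(names(sites), function(s) {
    do.call(rbind, lapply(methods, function(m) {
      d <- merge(as.data.frame(de[[s]][[m]]), as.data.frame(gold),
                 by = "gene_id")
      cc <- concordance(d$logfc_gold, d$logfc)
      data.frame(site = s, method = m, r = cc$pearson_r, icc = cc$icc,
                 n = cc$n, stringsAsFactors = FALSE)
    }))
  }))
  conc_p <- do.call(rbind, lapply(names(sites), function(s) {
    do.call(rbind, lapply(methods, function(m) {
      d <- merge(as.data.frame(de[[s]][[m]]), as.data.frame(gold),
                 by = "gene_id")
      ok <- is.finite(d$p) & is.finite(d$p_gold)
      cc <- pvalue_concordance(d$p_gold[ok], d$p[ok])
      data.frame(site = s, method = m, r = cc$pearson_r, icc = cc$icc,
                 n = cc$n, stringsAsFactors = FALSE)
    }))
  }))

  ## curves: pool per-gene points across sites before smoothing
  compression <- lapply(methods, function(m) {
    pts <- do.call(rbind, lapply(names(sites), function(s) {
      compression_per_gene(de[[s]][[m]], gold)
    }))
    lw <- lowess_curve(pts$ref_intensity, pts$compression, frac, iters)
    structure(list(points = pts, lowess = lw, method = m),
              class = "compression_curve")
  })
  names(compression) <- methods

  sd_curves <- lapply(methods, function(m) {
    i <- match(m, methods)
    pts <- do.call(rbind, lapply(names(sites), function(s) {
      ds <- sites[[s]]
      corrected <- correct_background(ds, grid$correction[i])
      tm <- if (grid$transform[i] == "log2") log2_transform(corrected) else
        glog_transform(corrected)
      tm <- global_median_normalize(tm)
      gene_tm <- average_replicate_spots(tm)
      ref_tm <- average_replicate_spots(log2_transform(correct_standard(ds)))
      sd_vs_intensity(gene_tm, ref_tm, frac, iters)$points
    }))
    lw <- lowess_curve(pts$mean_ref, pts$sd, frac, iters)
    structure(list(points = pts, lowess = lw, method = m),
              class = "sd_curve")
  })
  names(sd_curves) <- methods

  confusion <- lapply(c("log2", "glog", "hybrid"), function(tr) {
    m <- paste0(confusion_correction, "+", tr)
    calls <- do.call(c, lapply(names(sites), function(s) {
      d <- merge(as.data.frame(de[[s]][[m]]), as.data.frame(gold),
                 by = "gene_id")
      stats::setNames(
        abs(d$logfc) > thresholds$fc_threshold & d$p < thresholds$p_threshold,
        paste(s, d$gene_id))
    }))
    gcalls <- do.call(c, lapply(names(sites), function(s) {
      d <- merge(as.data.frame(de[[s]][[m]]), as.data.frame(gold),
                 by = "gene_id")
      abs(d$logfc_gold) > thresholds$fc_threshold &
        d$p_gold < thresholds$p_threshold
    }))
    confusion_metrics(gcalls, calls)
  })
  names(confusion) <- paste0(confusion_correction,
                             "+", c("log2", "glog", "hybrid"))

  structure(list(concordance_fc = conc_fc, concordance_p = conc_p,
                 compression = compression, sd_curves = sd_curves,
                 confusion = confusion, de = de, thresholds = thresholds),
            class = "preproc_report")
}

#' @export
print.preproc_report <- function(x, ...) {
  cat("Fold-change concordance with gold standard:\n")
  print(x$concordance_fc, row.names = FALSE)
  cat("\nProbit-scale p-value concordance:\n")
  print(x$concordance_p, row.names = FALSE)
  cat("\nVolcano confusion tables:\n")
  for (m in names(x$confusion)) {
    cat(m, ": ", sep = "")
    print(x$confusion[[m]])
  }
  invisible(x)
}
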