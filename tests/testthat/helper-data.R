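# fixtures built in code: a tiny hand-constructed dataset and small
# seeded simulations shared across test files

# one site, two arrays per condition, two replicate spots per gene;
# F - B per gene/array is controlled by `diffs` (genes x arrays)
tiny_dataset <- function(diffs = NULL, B = 200) {
  genes <- c("g1", "g2", "g3")
  arrays <- data.frame(array_id = c("a1", "a2", "b1", "b2"),
                       condition = c("A", "A", "B", "B"))
  if (is.null(diffs)) {
    diffs <- matrix(rep(c(300, 100, 50), 4), 3, 4)
  }
  rows <- expand.grid(spot_replicate = 1:2, gene_id = genes,
                      array_id = arrays$array_id,
                      stringsAsFactors = FALSE)
  rows$condition <- arrays$condition[match(rows$array_id, arrays$array_id)]
  rows$site <- "site1"
  idx <- (seq_len(nrow(rows)) - 1) %% 6
  rows$grid_row <- idx %/% 3
  rows$grid_col <- idx %% 3
  d <- diffs[cbind(match(rows$gene_id, genes),
                   match(rows$array_id, arrays$array_id))]
  rows$B <- B
  rows$F <- B + d
  spot_dataset(rows[, c("gene_id", "site", "condition", "array_id",
                        "spot_replicate", "grid_row", "grid_col", "F", "B")],
               n_spot_replicates = 2)
}

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 120, n_sites = 1, n_arrays_per_condition = 3,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# gene-level transformed matrix built directly from a value matrix
gene_matrix <- function(values, conditions) {
  design <- data.frame(array_id = paste0("arr", seq_along(conditions)),
                       site = "site1", condition = conditions,
                       stringsAsFactors = FALSE)
  colnames(values) <- design$array_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  transformed_matrix(values, design, "log2")
}

# corrected matrix (gene-level replicates) from the two-component error model
two_component_matrix <- function(n_genes = 300, n_per_cond = 3,
                                 eta_sd = 0.25, eps_sd = 60,
                                 offset = 0, scale = 1, seed = 7) {
  set.seed(seed)
  n_arr <- 2 * n_per_cond
  mu <- 2^stats::rnorm(n_genes, 7, 1.5)
  x <- matrix(rep(mu, n_arr) * exp(stats::rnorm(n_genes * n_arr, 0, eta_sd)) +
                stats::rnorm(n_genes * n_arr, 0, eps_sd),
              n_genes, n_arr)
  x <- (x + offset) * scale
  rownames(x) <- sprintf("g%03d", seq_len(n_genes))
  design <- data.frame(array_id = paste0("arr", seq_len(n_arr)),
                       site = "site1",
                       condition = rep(c("A", "B"), each = n_per_cond),
                       stringsAsFactors = FALSE)
  colnames(x) <- design$array_id
  structure(list(values = x, design = design, method = "standard",
                 params = list()),
            class = "corrected_matrix")
}
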