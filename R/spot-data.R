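#' Construct a spot-level dataset
#'
#' A `spot_dataset` holds one row per physical spot per array of a one-color
#' spotted microarray experiment: the foreground intensity `F` (mean pixel
#' intensity over the spotted region) and the local background intensity `B`
#' (mean pixel intensity of the surrounding region), together with the gene
#' identity, replicate-spot index, grid position, and the array's site and
#' condition (sample A or B).
#'
#' @param spots data.frame with columns `gene_id`, `site`, `condition`
#'   (`"A"` or `"B"`), `array_id`, `spot_replicate`, `grid_row`, `grid_col`,
#'   `F`, `B`.  Intensities are in arbitrary fluorescence units and must be
#'   non-negative.
#' @param n_spot_replicates number of replicate spots per gene per array
#'   (3 on triplicate-spotted cDNA arrays).
#'
#' @return An object of class `spot_dataset`: a list with elements `spots`
#'   and `n_spot_replicates`.
#' @export
spot_dataset <- function(spots, n_spot_replicates = max(spots$spot_replicate)) {
  x <- structure(
    list(
      spots = as.data.frame(spots),
      n_spot_replicates = as.integer(n_spot_replicates)
    ),
    class = "spot_dataset"
  )
  validate_spot_dataset(x)
}

required_spot_columns <- c(
  "gene_id", "site", "condition", "array_id", "spot_replicate",
  "grid_row", "grid_col", "F", "B"
)

#' Validate a spot dataset against its invariants
#'
#' Checks non-negative intensities, A/B conditions, a constant number of
#' replicate spots per (gene, array), unique grid coordinates within each
#' array, and a single (site, condition) per array.  Errors carry the first
#' offending row index so malformed producer output is locatable.
#'
#' @param x a `spot_dataset`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_spot_dataset <- function(x) {
  if (!inherits(x, "spot_dataset")) {
    stop("not a spot_dataset", call. = FALSE)
  }
  sp <- x$spots
  missing_cols <- setdiff(required_spot_columns, names(sp))
  if (length(missing_cols) > 0) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("F", "B")) {
    bad <- which(!is.finite(sp[[col]]) | sp[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative or non-finite %s at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  if (!all(sp$condition %in% c("A", "B"))) {
    bad <- which(!sp$condition %in% c("A", "B"))[1]
    stop(sprintf("condition must be \"A\" or \"B\" (row %d)", bad), call. = FALSE)
  }
  counts <- table(paste(sp$gene_id, sp$array_id, sep = "\r"))
  if (any(counts != x$n_spot_replicates)) {
    bad <- names(counts)[counts != x$n_spot_replicates][1]
    stop(sprintf("gene/array pair %s has %d spots, expected %d",
                 gsub("\r", "/", bad), counts[[bad]], x$n_spot_replicates),
         call. = FALSE)
  }
  pos <- paste(sp$array_id, sp$grid_row, sp$grid_col, sep = "\r")
  if (anyDuplicated(pos)) {
    stop(sprintf("duplicate grid position within an array (row %d)",
                 which(duplicated(pos))[1]), call. = FALSE)
  }
  per_array <- unique(sp[, c("array_id", "site", "condition")])
  if (anyDuplicated(per_array$array_id)) {
    stop("an array_id maps to more than one site/condition", call. = FALSE)
  }
  invisible(x)
}

#' Array-level design of a spot dataset
#'
#' @param dataset a `spot_dataset`.
#' @return data.frame with one row per array: `array_id`, `site`,
#'   `condition`, in order of first appearance.
#' @export
array_design <- function(dataset) {
  d <- unique(dataset$spots[, c("array_id", "site", "condition")])
  rownames(d) <- NULL
  d
}

## spot-level matrix: one row per (gene, replicate spot), one column per array
spot_matrix <- function(dataset, field = c("F", "B")) {
  field <- match.arg(field)
  sp <- dataset$spots
  row_key <- paste(sp$gene_id, sp$spot_replicate, sep = "#")
  rows <- unique(row_key)
  cols <- unique(sp$array_id)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(row_key, rows), match(sp$array_id, cols))] <- sp[[field]]
  m
}

## gene label of every row of a spot-level matrix ("gene#rep" row names)
row_genes <- function(m) sub("#[^#]*$", "", rownames(m))

#' Read a spot-level intensity table
#'
#' Long-format tab-delimited file, one row per spot per array, header naming
#' at least the columns of [spot_dataset()].  Missing entries are the literal
#' `NA` (not allowed in `F`/`B`).
#'
#' @param path file path.
#' @param n_spot_replicates optional; inferred from the data when `NULL`.
#' @return a validated `spot_dataset` with row order preserved.
#' @export
read_spot_table <- function(path, n_spot_replicates = NULL) {
  sp <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(gene_id = "character",
                                            site = "character",
                                            condition = "character",
                                            array_id = "character"))
  missing_cols <- setdiff(required_spot_columns, names(sp))
  if (length(missing_cols) > 0) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(n_spot_replicates)) {
    n_spot_replicates <- max(sp$spot_replicate)
  }
  spot_dataset(sp, n_spot_replicates)
}

#' Write a spot-level intensity table
#'
#' @param dataset a `spot_dataset`.
#' @param path output file path (tab-delimited, UTF-8, `NA` for missing).
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(dataset, path) {
  utils::write.table(dataset$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gold-standard table
#'
#' CSV with columns `gene_id`, `logfc_gold` (log2 fold-change of condition B
#' over condition A) and `p_gold` (two-sided p-value in (0, 1]), one row per
#' gene, as produced by a low-noise reference assay such as qPCR.
#'
#' @param path file path.
#' @return data.frame of class `gold_standard`.
#' @export
read_gold_standard <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(gene_id = "character"))
  gold_standard(g)
}

#' Construct and validate a gold standard
#'
#' @param g data.frame with columns `gene_id`, `logfc_gold`, `p_gold`.
#' @return `g` with class `gold_standard`.
#' @export
gold_standard <- function(g) {
  needed <- c("gene_id", "logfc_gold", "p_gold")
  missing_cols <- setdiff(needed, names(g))
  if (length(missing_cols) > 0) {
    stop("gold standard is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(g$gene_id)) {
    stop(sprintf("duplicate gene_id in gold standard: %s",
                 g$gene_id[duplicated(g$gene_id)][1]), call. = FALSE)
  }
  bad <- which(!is.finite(g$p_gold) | g$p_gold <= 0 | g$p_gold > 1)
  if (length(bad) > 0) {
    stop(sprintf("p_gold outside (0, 1] at row %d", bad[1]), call. = FALSE)
  }
  g <- as.data.frame(g)[, needed]
  class(g) <- c("gold_standard", "data.frame")
  g
}

#' Write a gold-standard table
#'
#' @param gold a `gold_standard`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.csv(as.data.frame(gold), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

## ---- matrix containers -----------------------------------------------------

new_value_matrix <- function(values, design, class, extra = list()) {
  stopifnot(is.matrix(values), identical(colnames(values), design$array_id))
  structure(c(list(values = values, design = design), extra), class = class)
}

#' Background-corrected intensity matrix
#'
#' Rows are spots (`gene#replicate`) or genes, columns are arrays; values are
#' background-corrected intensities in arbitrary fluorescence units and may
#' be negative under standard subtraction.
#'
#' @param values numeric matrix with array ids as column names.
#' @param design data.frame as from [array_design()], rows matching columns.
#' @param method one of `"standard"`, `"none"`, `"edwards"`, `"normexp"`.
#' @param params method parameter record (may be empty list).
#' @return object of class `corrected_matrix`.
#' @export
corrected_matrix <- function(values, design, method, params = list()) {
  method <- match.arg(method, c("standard", "none", "edwards", "normexp"))
  if (method %in% c("edwards", "normexp") &&
      any(values[is.finite(values)] <= 0)) {
    stop(sprintf("%s-corrected values must be strictly positive", method),
         call. = FALSE)
  }
  new_value_matrix(values, design, "corrected_matrix",
                   list(method = method, params = params))
}

#' Transformed intensity matrix on the log2 scale
#'
#' @param values numeric matrix (log2-scale, dimensionless); `NA` entries are
#'   allowed only under the log2 transform (where corrected intensity <= 0).
#' @param design data.frame as from [array_design()].
#' @param transform `"log2"` or `"glog"`.
#' @param glog_params a [glog_params()] object when `transform = "glog"`.
#' @param correction background-correction provenance string.
#' @return object of class `transformed_matrix`.
#' @export
transformed_matrix <- function(values, design, transform,
                               glog_params = NULL, correction = NA_character_) {
  transform <- match.arg(transform, c("log2", "glog"))
  if (transform == "glog") {
    if (is.null(glog_params)) stop("glog_params required for glog", call. = FALSE)
    if (anyNA(values)) stop("glog transform must not produce missing values",
                            call. = FALSE)
  }
  new_value_matrix(values, design, "transformed_matrix",
                   list(transform = transform, glog_params = glog_params,
                        correction = correction))
}

#' Write a gene-by-array matrix as TSV
#'
#' First column `gene_id` (the row names), one column per array id, `NA` for
#' missing values.
#'
#' @param m a `corrected_matrix` or `transformed_matrix` (or bare matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  values <- if (is.matrix(m)) m else m$values
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a gene-by-array matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with gene ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = list(gene_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @export
print.spot_dataset <- function(x, ...) {
  d <- array_design(x)
  cat(sprintf("spot_dataset: %d spots, %d genes, %d arrays (%d site(s)), %d replicate spot(s)/gene\n",
              nrow(x$spots), length(unique(x$spots$gene_id)), nrow(d),
              length(unique(d$site)), x$n_spot_replicates))
  invisible(x)
}
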