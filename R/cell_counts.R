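#' Cell-level count matrix with sample and condition annotation
#'
#' The central container of the package: a genes x cells matrix of non-negative
#' integer UMI counts, together with the cell-to-sample and sample-to-condition
#' maps that define the multi-subject, two-condition design.
#'
#' @param counts genes x cells matrix of non-negative integers. Row and column
#'   names, when absent, are taken from `gene_ids` / `cell_ids`.
#' @param cell_sample character or factor of length `ncol(counts)` giving the
#'   sample (subject) each cell belongs to.
#' @param sample_condition named character vector mapping each sample id to one
#'   of two condition labels.
#' @param gene_ids,cell_ids optional identifiers; default to the dimnames of
#'   `counts` or generated `gene1..`, `cell1..`.
#'
#' @return An object of class `cell_counts`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_sample` (factor) and `sample_condition`
#'   (named character, two levels).
#' @export
cell_counts <- function(counts, cell_sample, sample_condition,
                        gene_ids = NULL, cell_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  }
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length mismatch")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length mismatch")
  if (length(cell_sample) != ncol(counts)) {
    stop("cell_sample must annotate every cell exactly once")
  }
  cell_sample <- as.character(cell_sample)
  samples <- unique(cell_sample)
  if (is.null(names(sample_condition))) {
    stop("sample_condition must be named by sample id")
  }
  missing_s <- setdiff(samples, names(sample_condition))
  if (length(missing_s)) {
    stop("samples without a condition label: ", paste(missing_s, collapse = ", "))
  }
  sample_condition <- sample_condition[intersect(names(sample_condition), samples)]
  conds <- unique(unname(sample_condition))
  if (length(conds) > 2) stop("at most two condition labels are supported")
  dimnames(counts) <- list(gene_ids, cell_ids)
  storage.mode(counts) <- "double"
  structure(
    list(
      counts = counts,
      gene_ids = gene_ids,
      cell_ids = cell_ids,
      cell_sample = factor(cell_sample, levels = names(sample_condition)),
      sample_condition = sample_condition
    ),
    class = "cell_counts"
  )
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf(
    "cell_counts: %d genes x %d cells, %d samples, conditions: %s\n",
    nrow(x$counts), ncol(x$counts), nlevels(x$cell_sample),
    paste(unique(x$sample_condition), collapse = " vs ")
  ))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Condition label of each cell
#' @param x a `cell_counts` object
#' @return character vector of length `ncol(x)`
#' @export
cell_condition <- function(x) {
  unname(x$sample_condition[as.character(x$cell_sample)])
}

#' Per-cell library sizes (total counts)
#' @param x a `cell_counts` object
#' @return numeric vector named by cell id
#' @export
library_sizes <- function(x) colSums(x$counts)

#' Restrict a count matrix to a subset of cells and/or genes
#'
#' Samples that lose all their cells are dropped from the condition map.
#'
#' @param x a `cell_counts` object
#' @param cells,genes logical, integer or character index vectors
#' @return a `cell_counts` object
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  counts <- x$counts
  cs <- as.character(x$cell_sample)
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, x$cell_ids)
    counts <- counts[, cells, drop = FALSE]
    cs <- cs[cells]
  }
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, x$gene_ids)
    counts <- counts[genes, , drop = FALSE]
  }
  keep_s <- names(x$sample_condition)[names(x$sample_condition) %in% unique(cs)]
  cell_counts(counts, cs, x$sample_condition[keep_s])
}

# internal: list of cell indices per sample, in sample-metadata order
.cells_by_sample <- function(x) {
  split(seq_along(x$cell_sample), x$cell_sample, drop = FALSE)
}

# internal: validate a grouping vector against the two-condition design;
# returns a list(groups = factor with 2 levels, a, b)
.two_groups <- function(groups, n) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (length(groups) != n) stop("group vector length mismatch")
  if (any(table(groups) < 1)) stop("each group needs at least one observation")
  groups
}
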