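#' Write a count dataset as Matrix Market plus TSV metadata
#'
#' Produces `matrix.mtx` (sparse, 1-based coordinates), `genes.tsv` (gene
#' ids), `cells.tsv` (cell id, sample id, condition) and, when truth is
#' supplied, `truth.tsv` (gene id, category, logfc, is_ds) in `dir`.
#'
#' @param data a [cell_counts()] object.
#' @param dir output directory (created if absent).
#' @param truth optional truth data.frame.
#' @return `dir`, invisibly.
#' @export
write_count_data <- function(data, dir, truth = NULL) {
  stopifnot(inherits(data, "cell_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(data$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = data$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = data$cell_ids,
               sample_id = as.character(data$cell_sample),
               condition = cell_condition(data)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count dataset from the Matrix Market + TSV layout
#'
#' Counterpart of [write_count_data()]. Matrix Market triplets are 1-based;
#' the matrix is densified and validated against the cell metadata.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A [cell_counts()] object.
#' @export
read_count_data <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(Matrix::readMM(paths[1]))
  genes <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  cells <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m)) stop("genes.tsv does not match matrix rows")
  if (nrow(cells) != ncol(m)) {
    stop("cells.tsv does not match matrix columns; cells in the matrix ",
         "absent from metadata or vice versa")
  }
  if (any(m != round(m)) || any(m < 0)) {
    stop("matrix contains non-integer or negative values")
  }
  cond <- tapply(cells$condition, cells$sample_id, function(x) x[1])
  cell_counts(m, cells$sample_id,
              stats::setNames(as.character(cond), names(cond)),
              gene_ids = genes$gene_id, cell_ids = cells$cell_id)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each table as a TSV with stable column order and a
#' `manifest.tsv` recording file names, row counts, the seed and a
#' deterministic hash of the configuration string.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param seed integer seed to record.
#' @param config_string character describing the run configuration.
#' @return The manifest data.frame, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_,
                          config_string = "") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list")
  }
  files <- paste0(names(tables), ".tsv")
  for (i in seq_along(tables)) {
    utils::write.table(tables[[i]], file.path(out_dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  manifest <- data.frame(
    file = files,
    n_rows = vapply(tables, nrow, integer(1)),
    seed = seed,
    config_hash = .string_hash(config_string),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# small stable string hash (polynomial rolling, modulus 2^31 - 1)
.string_hash <- function(s) {
  if (!nchar(s)) return("0")
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  sprintf("%d", h)
}
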