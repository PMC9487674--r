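#' Per-method gene (and sample) filtering rules
#'
#' The filtering strategies the compared method families apply before
#' testing:
#' \describe{
#'   \item{nonexpressed}{drop genes with zero counts in every cell.}
#'   \item{min_cells_expressing}{drop genes detected in fewer than `k` cells
#'     (the count-GLM convention, `k = 3`).}
#'   \item{counts_per_cell}{drop genes whose total count divided by the number
#'     of cells is below `t` (default 0.005).}
#'   \item{min_cells_expressing_and_min_cells_per_sample}{drop samples with
#'     fewer than `m` cells (default 10), then genes detected in fewer than
#'     `k` cells (default 20).}
#'   \item{expressing_lt_n_subjects}{drop genes detected in fewer cells than
#'     there are samples.}
#' }
#'
#' @param data a [cell_counts()] object.
#' @param rule one of the rule names above.
#' @param k,t,m rule parameters (see Details).
#' @return A list with `data` (the filtered `cell_counts`) and `report` (a
#'   list with `rule`, `genes_in`, `genes_out`, `removed_genes`,
#'   `removed_samples`).
#' @export
apply_gene_filter <- function(data,
                              rule = c("nonexpressed",
                                       "min_cells_expressing",
                                       "counts_per_cell",
                                       "min_cells_expressing_and_min_cells_per_sample",
                                       "expressing_lt_n_subjects"),
                              k = NULL, t = NULL, m = NULL) {
  stopifnot(inherits(data, "cell_counts"))
  rule <- match.arg(rule)
  removed_samples <- character(0)
  if (rule == "min_cells_expressing_and_min_cells_per_sample") {
    if (is.null(m)) m <- 10
    n_per_sample <- table(data$cell_sample)
    bad <- names(n_per_sample)[n_per_sample < m]
    if (length(bad)) {
      removed_samples <- bad
      keep_cells <- !(as.character(data$cell_sample) %in% bad)
      if (!any(keep_cells)) stop("filter removed every sample")
      data <- subset_cells(data, cells = which(keep_cells))
    }
  }
  n_expressing <- rowSums(data$counts > 0)
  keep <- switch(rule,
    nonexpressed = n_expressing > 0,
    min_cells_expressing = {
      if (is.null(k)) k <- 3
      n_expressing >= k
    },
    counts_per_cell = {
      if (is.null(t)) t <- 0.005
      rowSums(data$counts) / ncol(data$counts) >= t
    },
    min_cells_expressing_and_min_cells_per_sample = {
      if (is.null(k)) k <- 20
      n_expressing >= k
    },
    expressing_lt_n_subjects = n_expressing >= nlevels(data$cell_sample)
  )
  report <- list(
    rule = rule,
    genes_in = length(keep),
    genes_out = sum(keep),
    removed_genes = data$gene_ids[!keep],
    removed_samples = removed_samples
  )
  out <- if (all(keep)) data else subset_cells(data, genes = which(keep))
  list(data = out, report = report)
}
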