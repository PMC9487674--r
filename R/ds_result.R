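#' Construct a per-gene differential-state test result
#'
#' @param gene_ids character vector of gene identifiers.
#' @param p_value numeric in \[0, 1\] or NA for untested genes.
#' @param effect per-gene effect estimate (log2 fold change scale where
#'   applicable).
#' @param tested logical mask of genes the method actually tested.
#' @param method method name.
#' @param params list of method metadata (aggregation, normalization, latent
#'   terms, ...).
#' @return A data.frame of class `ds_result` with attributes `method` and
#'   `params`.
#' @export
ds_result <- function(gene_ids, p_value, effect, tested, method,
                      params = list()) {
  stopifnot(length(gene_ids) == length(p_value),
            length(gene_ids) == length(tested))
  if (length(effect) != length(gene_ids)) effect <- rep(NA_real_, length(gene_ids))
  bad <- !is.na(p_value) & (p_value < 0 | p_value > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  if (any(!tested & !is.na(p_value))) {
    stop("p-values present for untested genes")
  }
  out <- data.frame(gene_id = as.character(gene_ids),
                    p_value = as.numeric(p_value),
                    effect = as.numeric(effect),
                    tested = as.logical(tested),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "params") <- params
  class(out) <- c("ds_result", "data.frame")
  out
}

# expand a result computed on a filtered gene set back to the full gene set
.expand_result <- function(res, all_gene_ids) {
  idx <- match(all_gene_ids, res$gene_id)
  ds_result(
    gene_ids = all_gene_ids,
    p_value = res$p_value[idx],
    effect = res$effect[idx],
    tested = !is.na(idx) & res$tested[idx],
    method = attr(res, "method"),
    params = attr(res, "params")
  )
}
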