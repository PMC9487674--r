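#' Log-normalize single-cell counts
#'
#' The standard single-cell transformation: each count is scaled by its cell's
#' library size, multiplied by `scale` and log-transformed with a pseudocount
#' of 1, i.e. `ln(1 + count * scale / libsize)`.
#'
#' @param data a [cell_counts()] object.
#' @param scale scale factor; default 10000.
#' @return genes x cells numeric matrix with the dimnames of the input.
#' @export
lognormalize <- function(data, scale = 1e4) {
  stopifnot(inherits(data, "cell_counts"))
  lib <- library_sizes(data)
  if (any(lib == 0)) {
    stop("zero library size for cell(s): ",
         paste(data$cell_ids[lib == 0], collapse = ", "))
  }
  log1p(sweep(data$counts, 2, scale / lib, "*"))
}

#' Pseudobulk by summing raw counts within samples
#'
#' @param data a [cell_counts()] object with at least one cell per sample.
#' @return A `pseudobulk` object: list with `values` (genes x samples),
#'   `aggregation = "sum"`, `normalization = "raw"` and `sample_condition`.
#' @export
aggregate_sum <- function(data) {
  stopifnot(inherits(data, "cell_counts"))
  by_sample <- .cells_by_sample(data)
  if (any(lengths(by_sample) == 0)) stop("every sample needs >= 1 cell")
  values <- vapply(by_sample, function(idx) {
    rowSums(data$counts[, idx, drop = FALSE])
  }, numeric(nrow(data$counts)))
  rownames(values) <- data$gene_ids
  .pseudobulk(values, "sum", "raw", data$sample_condition)
}

#' Pseudobulk by averaging normalized values within samples
#'
#' @param normalized genes x cells matrix aligned with `data` (typically from
#'   [lognormalize()]).
#' @param data the [cell_counts()] object supplying the cell-to-sample map.
#' @return A `pseudobulk` object tagged `aggregation = "mean"`,
#'   `normalization = "lognorm_mean"`.
#' @export
aggregate_mean <- function(normalized, data) {
  stopifnot(inherits(data, "cell_counts"))
  if (!all(dim(normalized) == dim(data$counts))) {
    stop("normalized matrix does not align with the count matrix")
  }
  by_sample <- .cells_by_sample(data)
  values <- vapply(by_sample, function(idx) {
    rowMeans(normalized[, idx, drop = FALSE])
  }, numeric(nrow(normalized)))
  rownames(values) <- data$gene_ids
  .pseudobulk(values, "mean", "lognorm_mean", data$sample_condition)
}

.pseudobulk <- function(values, aggregation, normalization, sample_condition) {
  structure(
    list(values = values, aggregation = aggregation,
         normalization = normalization,
         sample_condition = sample_condition[colnames(values)]),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk (%s, %s): %d genes x %d samples\n",
              x$aggregation, x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Scaling factors for summed pseudobulk counts, computed against a reference
#' column (the sample whose 75th count-fraction percentile is closest to the
#' mean across samples). Gene-wise log-ratios (M) are trimmed by 30\% and
#' absolute log-intensities (A) by 5\% on each side; the factor is the
#' precision-weighted mean of the surviving M values, and factors are rescaled
#' so their product is 1.
#'
#' @param pb a sum-aggregated `pseudobulk` object with >= 2 samples.
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @return Named positive numeric vector of per-sample factors (product 1).
#' @export
tmm_factors <- function(pb, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (pb$aggregation != "sum") stop("TMM expects sum-aggregated counts")
  x <- pb$values
  if (ncol(x) < 2) stop("TMM needs at least two samples")
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with zero total count")
  f75 <- apply(x, 2, function(col) stats::quantile(col / sum(col), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

# TMM factor of obs against ref (both raw count columns)
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_o <- obs[keep] / n_obs
  p_r <- ref[keep] / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  # asymptotic variance of M (delta method), used as inverse weight
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  # midranks keep the trim invariant to gene order under ties
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
           rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) 1 else 2^f
}

#' Median-of-ratios size factors
#'
#' For each gene expressed in every sample, the ratio of its count to its
#' geometric mean across samples is formed; a sample's size factor is the
#' median of these ratios.
#'
#' @param pb a sum-aggregated `pseudobulk` object.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
median_of_ratios_factors <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (pb$aggregation != "sum") stop("median-of-ratios expects summed counts")
  x <- pb$values
  all_pos <- rowSums(x > 0) == ncol(x)
  if (!any(all_pos)) stop("no gene with nonzero counts in all samples")
  logx <- log(x[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logx)
  f <- apply(logx, 2, function(col) exp(stats::median(col - log_geo)))
  stats::setNames(f, colnames(x))
}

#' log2 counts per million with effective library sizes
#'
#' CPM on summed pseudobulk counts using library sizes multiplied by
#' normalization factors, with a prior count of 0.5 before the log2.
#'
#' @param pb a sum-aggregated `pseudobulk` object.
#' @param factors per-sample normalization factors, e.g. from [tmm_factors()].
#' @param prior_count pseudocount added before the log (default 0.5).
#' @return A `pseudobulk` object tagged `normalization = "tmm_cpm_log2"`.
#' @export
cpm_log2 <- function(pb, factors = tmm_factors(pb), prior_count = 0.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  eff <- colSums(pb$values) * factors[colnames(pb$values)]
  values <- log2(sweep(pb$values + prior_count, 2, (eff + 1) / 1e6, "/"))
  out <- .pseudobulk(values, pb$aggregation, "tmm_cpm_log2",
                     pb$sample_condition)
  out
}
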