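#' Configuration of a hierarchical negative-binomial simulation
#'
#' Describes one two-condition, multi-subject dataset drawn from the
#' reference-free generative model: per-gene baseline log-means, a gamma
#' multiplicative subject effect controlled by `sample_overdispersion`, and
#' negative-binomial cell-level counts with quadratic overdispersion
#' `cell_overdispersion` (variance mu * (1 + phi * mu)).
#'
#' @param n_samples_total even integer >= 4; split equally into two conditions.
#' @param avg_cells_per_sample positive integer, expected cells per sample.
#' @param cell_count_distribution `"poisson"` (balanced cell allocation) or
#'   `"negbinomial"` (imbalanced; NB with size 2).
#' @param cell_overdispersion phi > 0, cell-level NB overdispersion.
#' @param sample_overdispersion theta > 0, gamma shape of the subject effect
#'   (mean 1, variance 1/theta): 0.1 = strong subject variation, 100 = almost
#'   none.
#' @param n_genes number of genes.
#' @param n_de_genes number of genes given a non-zero log2 fold change.
#' @param logfc_magnitude_range length-2 numeric, |log2FC| range for DE genes.
#' @param baseline_log_mean_range length-2 numeric, natural-log per-cell mean
#'   expression range.
#' @param seed integer RNG seed.
#'
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_samples_total = 14,
                       avg_cells_per_sample = 500,
                       cell_count_distribution = c("poisson", "negbinomial"),
                       cell_overdispersion = 0.2,
                       sample_overdispersion = 1,
                       n_genes = 2000,
                       n_de_genes = 100,
                       logfc_magnitude_range = c(0.5, 2.0),
                       baseline_log_mean_range = c(-4, 2),
                       seed = 1L) {
  cell_count_distribution <- match.arg(cell_count_distribution)
  n_samples_total <- as.integer(n_samples_total)
  if (n_samples_total < 4 || n_samples_total %% 2 != 0) {
    stop("n_samples_total must be an even integer >= 4")
  }
  if (avg_cells_per_sample < 1) stop("avg_cells_per_sample must be positive")
  if (cell_overdispersion <= 0) stop("cell_overdispersion must be positive")
  if (sample_overdispersion <= 0) stop("sample_overdispersion must be positive")
  n_genes <- as.integer(n_genes)
  n_de_genes <- as.integer(n_de_genes)
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_de_genes < 0 || n_de_genes > n_genes) {
    stop("n_de_genes must lie in [0, n_genes]")
  }
  if (length(logfc_magnitude_range) != 2 ||
      logfc_magnitude_range[1] < 0 ||
      diff(logfc_magnitude_range) < 0) {
    stop("logfc_magnitude_range must be a non-negative, non-decreasing interval")
  }
  if (length(baseline_log_mean_range) != 2 ||
      diff(baseline_log_mean_range) < 0) {
    stop("baseline_log_mean_range must be a non-decreasing interval")
  }
  structure(
    list(
      n_samples_total = n_samples_total,
      avg_cells_per_sample = as.integer(avg_cells_per_sample),
      cell_count_distribution = cell_count_distribution,
      cell_overdispersion = cell_overdispersion,
      sample_overdispersion = sample_overdispersion,
      n_genes = n_genes,
      n_de_genes = n_de_genes,
      logfc_magnitude_range = as.numeric(logfc_magnitude_range),
      baseline_log_mean_range = as.numeric(baseline_log_mean_range),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Full factorial grid of simulation configurations
#'
#' Expands the Cartesian product of the five varied parameters into one
#' `sim_config` per combination. The default lists reproduce the benchmark
#' grid of 10 sample counts x 4 cell counts x 2 cell-count distributions x
#' 4 cell overdispersions x 4 sample overdispersions = 1280 configurations.
#' Each configuration receives a distinct deterministic seed derived from
#' `master_seed`.
#'
#' @param samples sample-count levels (even integers >= 4).
#' @param avg_cells average-cells-per-sample levels.
#' @param distributions cell-count distribution levels.
#' @param cell_od cell overdispersion levels.
#' @param sample_od sample overdispersion (gamma shape) levels.
#' @param master_seed integer from which per-configuration seeds are derived.
#' @param ... further arguments passed to [sim_config()] (e.g. `n_genes`).
#'
#' @return A list of `sim_config` objects, one per grid point.
#' @examples
#' length(make_grid())  # 1280
#' @export
make_grid <- function(samples = c(6, 8, 10, 12, 14, 16, 18, 20, 30, 40),
                      avg_cells = c(100, 500, 1000, 2000),
                      distributions = c("poisson", "negbinomial"),
                      cell_od = c(0.05, 0.10, 0.20, 0.50),
                      sample_od = c(0.1, 1, 10, 100),
                      master_seed = 1L, ...) {
  if (!length(samples) || !length(avg_cells) || !length(distributions) ||
      !length(cell_od) || !length(sample_od)) {
    stop("all parameter lists must be non-empty")
  }
  if (any(samples %% 2 != 0) || any(samples < 4)) {
    stop("sample counts must be even integers >= 4")
  }
  grid <- expand.grid(
    n_samples_total = samples,
    avg_cells_per_sample = avg_cells,
    cell_count_distribution = distributions,
    cell_overdispersion = cell_od,
    sample_overdispersion = sample_od,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    sim_config(
      n_samples_total = grid$n_samples_total[i],
      avg_cells_per_sample = grid$avg_cells_per_sample[i],
      cell_count_distribution = grid$cell_count_distribution[i],
      cell_overdispersion = grid$cell_overdispersion[i],
      sample_overdispersion = grid$sample_overdispersion[i],
      seed = derive_seed(master_seed, i),
      ...
    )
  })
}

#' Derive a deterministic child seed from a master seed
#'
#' A Lehmer-style mixing step on the modulus 2^31 - 1; stable across platforms
#' and safe in double precision. Used so every dataset, repetition and
#' bootstrap in the package has its own reproducible stream.
#'
#' @param master_seed integer master seed.
#' @param index positive integer identifying the child stream.
#' @return An integer between 1 and 2^31 - 2.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  x <- (abs(as.double(master_seed)) %% m)
  x <- (x * 48271 + as.double(index) * 16807 + 12345) %% m
  # two multiplicative rounds decorrelate consecutive indices
  x <- (x * 48271) %% m
  as.integer(if (x == 0) 1 else x)
}
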