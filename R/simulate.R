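#' Simulate a multi-subject two-condition scRNA-seq dataset
#'
#' Draws counts from the hierarchical negative-binomial generative model. For
#' gene g the baseline natural-log mean beta0_g is uniform on
#' `baseline_log_mean_range`. Each (gene, sample) pair receives a
#' multiplicative subject effect u_gs ~ Gamma(shape = theta, rate = theta)
#' (mean 1, variance 1/theta, theta = `sample_overdispersion`). A cell c in
#' sample s of condition B has mean
#' mu = exp(beta0_g) * u_gs * 2^logfc_g (condition A omits the fold-change
#' term), and its count is NB with variance mu * (1 + phi * mu),
#' phi = `cell_overdispersion`. Exactly `n_de_genes` genes get |log2FC| drawn
#' uniformly from `logfc_magnitude_range` with a random sign; all others have
#' logfc 0. Cells per sample are Poisson(avg) or NB(mean = avg, size = 2).
#'
#' @param config a [sim_config()] object.
#' @return A list with `data` (a [cell_counts()] object) and `truth` (a
#'   data.frame with columns `gene_id`, `category` in \{nonDE, DE\}, `logfc`
#'   on the log2 scale, `is_ds`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples_total = 6, n_genes = 50,
#'                                    n_de_genes = 5, avg_cells_per_sample = 20))
#' table(sim$truth$category)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  S <- config$n_samples_total
  theta <- config$sample_overdispersion
  phi <- config$cell_overdispersion

  beta0 <- stats::runif(G, config$baseline_log_mean_range[1],
                        config$baseline_log_mean_range[2])
  logfc <- numeric(G)
  de_idx <- integer(0)
  if (config$n_de_genes > 0) {
    de_idx <- sort(sample.int(G, config$n_de_genes))
    mag <- stats::runif(config$n_de_genes, config$logfc_magnitude_range[1],
                        config$logfc_magnitude_range[2])
    sgn <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
    logfc[de_idx] <- mag * sgn
  }

  n_cells <- .draw_cell_counts(S, config$avg_cells_per_sample,
                               config$cell_count_distribution)
  sample_ids <- sprintf("sample%02d", seq_len(S))
  condition <- rep(c("A", "B"), each = S / 2)
  names(condition) <- sample_ids

  counts <- matrix(0, nrow = G, ncol = sum(n_cells))
  cell_sample <- rep(sample_ids, times = n_cells)
  col0 <- 0L
  base_mu <- exp(beta0)
  for (s in seq_len(S)) {
    nc <- n_cells[s]
    u <- stats::rgamma(G, shape = theta, rate = theta)
    mu_s <- base_mu * u
    if (condition[s] == "B") mu_s <- mu_s * 2^logfc
    counts[, col0 + seq_len(nc)] <-
      stats::rnbinom(G * nc, size = 1 / phi, mu = rep(mu_s, times = nc))
    col0 <- col0 + nc
  }
  gene_ids <- sprintf("gene%04d", seq_len(G))
  truth <- data.frame(
    gene_id = gene_ids,
    category = ifelse(seq_len(G) %in% de_idx, "DE", "nonDE"),
    logfc = logfc,
    is_ds = seq_len(G) %in% de_idx,
    stringsAsFactors = FALSE
  )
  data <- cell_counts(counts, cell_sample, condition, gene_ids = gene_ids)
  list(data = data, truth = truth)
}

# cells per sample; at least 1 so no sample is empty
.draw_cell_counts <- function(n_samples, avg, distribution) {
  n <- switch(distribution,
    poisson = stats::rpois(n_samples, avg),
    negbinomial = stats::rnbinom(n_samples, size = 2, mu = avg),
    stop("unknown cell_count_distribution: ", distribution)
  )
  pmax(n, 1L)
}

#' Configuration of the DS-category simulation
#'
#' Parameters of the two-component (low/high) extension of the generative
#' model that emulates the six expression categories: EE and EP (no
#' differential state) and the four DS types DE, DP, DM and DB. Expression of
#' a gene in a cell is drawn from a low component at natural-log mean beta0 or
#' a high component at beta0 + mixture_gap * log(2) (i.e. `mixture_gap` is on
#' the log2 scale); the category decides how the components and their mixing
#' weights differ between conditions.
#'
#' @param n_genes number of genes.
#' @param n_samples_total even integer >= 4.
#' @param avg_cells_per_sample expected cells per sample (Poisson).
#' @param category_fractions named numeric over EE, EP, DE, DP, DM, DB summing
#'   to 1. Default: 2.5 percent for each DS category (10 percent DS in total),
#'   the remainder split 80/10 between EE and EP.
#' @param cluster_logfc positive log2 fold change of the DE category and the
#'   scale of the low/high separation; the benchmark uses 0.5, 1 and 1.25.
#' @param sample_overdispersion,cell_overdispersion as in [sim_config()].
#' @param mixture_gap log2 distance between the low and high component means;
#'   defaults to `3 * cluster_logfc`.
#' @param dp_proportions mixing weights (low, high) of condition A for DP
#'   genes; condition B uses the reversed pair.
#' @param baseline_log_mean_range natural-log range of the low-component mean.
#' @param seed integer RNG seed.
#' @return A validated `category_config` object.
#' @export
category_config <- function(n_genes = 2000,
                            n_samples_total = 8,
                            avg_cells_per_sample = 200,
                            category_fractions = c(EE = 0.80, EP = 0.10,
                                                   DE = 0.025, DP = 0.025,
                                                   DM = 0.025, DB = 0.025),
                            cluster_logfc = 1,
                            sample_overdispersion = 1,
                            cell_overdispersion = 0.2,
                            mixture_gap = 3 * cluster_logfc,
                            dp_proportions = c(0.3, 0.7),
                            baseline_log_mean_range = c(-4, 2),
                            seed = 1L) {
  need <- c("EE", "EP", "DE", "DP", "DM", "DB")
  if (!all(need %in% names(category_fractions))) {
    stop("category_fractions must name all of ", paste(need, collapse = ", "))
  }
  category_fractions <- category_fractions[need]
  if (abs(sum(category_fractions) - 1) > 1e-12) {
    stop("category fractions must sum to 1")
  }
  if (any(category_fractions < 0)) stop("category fractions must be >= 0")
  if (cluster_logfc <= 0) stop("cluster_logfc must be positive")
  if (mixture_gap <= 0) stop("mixture_gap must be positive")
  if (length(dp_proportions) != 2 || abs(sum(dp_proportions) - 1) > 1e-12) {
    stop("dp_proportions must be two mixing fractions summing to 1")
  }
  n_samples_total <- as.integer(n_samples_total)
  if (n_samples_total < 4 || n_samples_total %% 2 != 0) {
    stop("n_samples_total must be an even integer >= 4")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_samples_total = n_samples_total,
      avg_cells_per_sample = as.integer(avg_cells_per_sample),
      category_fractions = category_fractions,
      cluster_logfc = cluster_logfc,
      sample_overdispersion = sample_overdispersion,
      cell_overdispersion = cell_overdispersion,
      mixture_gap = mixture_gap,
      dp_proportions = as.numeric(dp_proportions),
      baseline_log_mean_range = as.numeric(baseline_log_mean_range),
      seed = as.integer(seed)
    ),
    class = "category_config"
  )
}

#' Simulate a dataset with the six DS/non-DS expression categories
#'
#' Per-gene two-component scheme on the log-mean scale (low component at
#' beta0, high at beta0 + mixture_gap on log2): EE is unimodal low in both
#' conditions; EP is the same 50/50 low/high mixture in both; DE shifts
#' condition B by +/- `cluster_logfc`; DP mixes with `dp_proportions` in A and
#' the reversed proportions in B; DM is unimodal low in A and unimodal high in
#' B; DB is unimodal at the midpoint in A and a 50/50 mixture in B. Cell- and
#' sample-level overdispersion act as in [simulate_dataset()]. Category counts
#' follow `category_fractions` exactly (largest-remainder rounding).
#'
#' @param config a [category_config()] object.
#' @return A list with `data` (a [cell_counts()]) and `truth` (data.frame with
#'   `gene_id`, `category`, `logfc` = analytic log2 ratio of condition mean
#'   expressions, `is_ds`).
#' @export
simulate_category_dataset <- function(config) {
  stopifnot(inherits(config, "category_config"))
  set.seed(config$seed)
  G <- config$n_genes
  S <- config$n_samples_total
  theta <- config$sample_overdispersion
  phi <- config$cell_overdispersion
  gap_ln <- config$mixture_gap * log(2)

  n_per_cat <- .largest_remainder(config$category_fractions, G)
  category <- sample(rep(names(n_per_cat), times = n_per_cat))

  beta0 <- stats::runif(G, config$baseline_log_mean_range[1],
                        config$baseline_log_mean_range[2])
  de_sign <- sample(c(-1, 1), G, replace = TRUE)

  # per-condition mixture spec: weights (low, high) and component log-means
  low <- beta0
  high <- beta0 + gap_ln
  mid <- beta0 + gap_ln / 2
  mix <- .category_mixtures(category, low, high, mid, de_sign,
                            config$cluster_logfc, config$dp_proportions)

  n_cells <- pmax(stats::rpois(S, config$avg_cells_per_sample), 1L)
  sample_ids <- sprintf("sample%02d", seq_len(S))
  condition <- rep(c("A", "B"), each = S / 2)
  names(condition) <- sample_ids

  counts <- matrix(0, nrow = G, ncol = sum(n_cells))
  cell_sample <- rep(sample_ids, times = n_cells)
  col0 <- 0L
  for (s in seq_len(S)) {
    nc <- n_cells[s]
    u <- stats::rgamma(G, shape = theta, rate = theta)
    if (condition[s] == "A") {
      w_high <- mix$wA_high; m_low <- mix$A_low; m_high <- mix$A_high
    } else {
      w_high <- mix$wB_high; m_low <- mix$B_low; m_high <- mix$B_high
    }
    for (j in seq_len(nc)) {
      pick_high <- stats::runif(G) < w_high
      mu <- exp(ifelse(pick_high, m_high, m_low)) * u
      counts[, col0 + j] <- stats::rnbinom(G, size = 1 / phi, mu = mu)
    }
    col0 <- col0 + nc
  }

  gene_ids <- sprintf("gene%04d", seq_len(G))
  mean_A <- (1 - mix$wA_high) * exp(mix$A_low) + mix$wA_high * exp(mix$A_high)
  mean_B <- (1 - mix$wB_high) * exp(mix$B_low) + mix$wB_high * exp(mix$B_high)
  logfc <- log2(mean_B / mean_A)
  logfc[category %in% c("EE", "EP")] <- 0
  is_ds <- category %in% c("DE", "DP", "DM", "DB")
  truth <- data.frame(gene_id = gene_ids, category = category,
                      logfc = logfc, is_ds = is_ds, stringsAsFactors = FALSE)
  data <- cell_counts(counts, cell_sample, condition, gene_ids = gene_ids)
  list(data = data, truth = truth)
}

# mixture weights (probability of the high component) and component log-means
# per condition, for each gene, given its category
.category_mixtures <- function(category, low, high, mid, de_sign,
                               cluster_logfc, dp) {
  G <- length(category)
  wA <- numeric(G); wB <- numeric(G)
  A_low <- low; A_high <- high
  B_low <- low; B_high <- high
  ep <- category == "EP"
  wA[ep] <- 0.5; wB[ep] <- 0.5
  de <- category == "DE"
  shift <- de_sign * cluster_logfc * log(2)
  B_low[de] <- low[de] + shift[de]
  B_high[de] <- high[de] + shift[de]
  dp_i <- category == "DP"
  wA[dp_i] <- dp[2]           # weight on the high component in A
  wB[dp_i] <- dp[1]           # reversed in B
  dm <- category == "DM"
  wB[dm] <- 1                 # A stays unimodal low (wA 0)
  db <- category == "DB"
  A_low[db] <- mid[db]        # A unimodal at the midpoint
  A_high[db] <- mid[db]
  wB[db] <- 0.5
  list(wA_high = wA, wB_high = wB,
       A_low = A_low, A_high = A_high, B_low = B_low, B_high = B_high)
}

# integer allocation of n items to fractions, exact total
.largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Impose an imbalanced cell allocation by even-interval subsampling
#'
#' Builds evenly spaced retention proportions from `min_prop` to `max_prop`
#' (one per sample), permutes them randomly across samples, and keeps
#' `max(1, floor(proportion * n_cells))` cells per sample, sampled without
#' replacement. The gene set is unchanged.
#'
#' @param data a [cell_counts()] object.
#' @param min_prop,max_prop retention proportion bounds, 0 < min <= max <= 1.
#' @param seed integer RNG seed.
#' @return A `cell_counts` object with the retained cells.
#' @export
subsample_imbalance <- function(data, min_prop = 0.2, max_prop = 1, seed = 1L) {
  stopifnot(inherits(data, "cell_counts"))
  if (!(min_prop > 0 && min_prop <= max_prop && max_prop <= 1)) {
    stop("need 0 < min_prop <= max_prop <= 1")
  }
  set.seed(seed)
  by_sample <- .cells_by_sample(data)
  S <- length(by_sample)
  props <- if (S == 1) max_prop else seq(min_prop, max_prop, length.out = S)
  props <- sample(props)
  keep <- unlist(lapply(seq_len(S), function(s) {
    cells <- by_sample[[s]]
    k <- max(1L, floor(props[s] * length(cells)))
    if (k == 0) {
      stop("sample ", names(by_sample)[s], " would retain 0 cells")
    }
    sort(sample(cells, k))
  }), use.names = FALSE)
  subset_cells(data, cells = keep)
}
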