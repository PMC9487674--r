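#' Run the simulation benchmark over a configuration grid
#'
#' For every configuration: simulate a dataset, run every requested method,
#' restrict to the genes tested by all methods, BH-adjust per dataset, and
#' evaluate against the simulation truth. Method failures on a dataset are
#' recorded (NA metrics) rather than fatal.
#'
#' @param configs list of [sim_config()] objects (e.g. from [make_grid()]).
#' @param methods character vector of [ds_methods()] names.
#' @param alpha FDR cutoff for the confusion metrics.
#' @return A data.frame with one EvalSummary row per (configuration, method).
#' @export
run_benchmark_grid <- function(configs, methods, alpha = 0.05) {
  if (!length(configs) || !length(methods)) {
    stop("configs and methods must be non-empty")
  }
  rows <- vector("list", length(configs) * length(methods))
  n <- 0
  for (ci in seq_along(configs)) {
    sim <- simulate_dataset(configs[[ci]])
    ds_id <- sprintf("config%04d", ci)
    results <- list()
    for (m in methods) {
      results[[m]] <- tryCatch(
        run_ds_method(sim$data, m, seed = derive_seed(configs[[ci]]$seed, 7)),
        error = function(e) {
          warning("method ", m, " failed on ", ds_id, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
    }
    ok <- !vapply(results, is.null, logical(1))
    genes <- if (any(ok)) common_genes(results[ok]) else character(0)
    for (m in methods) {
      n <- n + 1
      rows[[n]] <- if (!is.null(results[[m]])) {
        evaluate_result(results[[m]], sim$truth, genes = genes,
                        alpha = alpha, dataset_id = ds_id)
      } else {
        data.frame(method = m, dataset_id = ds_id, auroc = NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_,
                   precision = NA_real_, f1 = NA_real_, mcc = NA_real_,
                   n_genes_evaluated = 0L, n_significant = 0L,
                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Mock comparison: testing between random groups of same-condition samples
#'
#' Samples from a single condition are repeatedly split uniformly at random
#' into two balanced mock groups (the larger group takes the extra sample
#' when the count is odd); every finding is by construction a false
#' positive. Each method is run per repetition; the reported proportion is
#' significant genes (BH q <= `alpha`) divided by the genes tested by all
#' methods in that repetition.
#'
#' @param data a [cell_counts()] object restricted to one condition
#'   (>= 4 samples).
#' @param methods character vector of method names.
#' @param n_rep number of random splits (default 30).
#' @param master_seed integer; per-repetition seeds are derived from it.
#' @param alpha FDR cutoff.
#' @return A data.frame with columns `repetition`, `seed`, `method`,
#'   `n_common_genes`, `n_significant`, `proportion_significant`.
#' @export
mock_comparison <- function(data, methods, n_rep = 30, master_seed = 1L,
                            alpha = 0.05) {
  stopifnot(inherits(data, "cell_counts"))
  samples <- names(data$sample_condition)
  if (length(unique(data$sample_condition)) != 1) {
    stop("mock comparison expects data from a single condition")
  }
  if (length(samples) < 4) stop("need >= 4 samples")
  n_half <- length(samples) %/% 2
  if (n_half < 2) stop("need >= 2 samples per mock group")
  rows <- list()
  for (rep_i in seq_len(n_rep)) {
    seed_i <- derive_seed(master_seed, rep_i)
    set.seed(seed_i)
    shuffled <- sample(samples)
    mock <- stats::setNames(
      rep(c("mockA", "mockB"), c(n_half, length(samples) - n_half)),
      shuffled)[samples]
    results <- list()
    for (m in methods) {
      results[[m]] <- tryCatch(
        run_ds_method(data, m, groups = mock,
                      seed = derive_seed(seed_i, 13)),
        error = function(e) NULL)
    }
    ok <- !vapply(results, is.null, logical(1))
    genes <- if (any(ok)) common_genes(results[ok]) else character(0)
    for (m in methods) {
      r <- results[[m]]
      if (is.null(r)) {
        rows[[length(rows) + 1]] <- data.frame(
          repetition = rep_i, seed = seed_i, method = m,
          n_common_genes = length(genes), n_significant = NA_integer_,
          proportion_significant = NA_real_, stringsAsFactors = FALSE)
        next
      }
      p <- r$p_value[match(genes, r$gene_id)]
      q <- bh_adjust(p)
      n_sig <- sum(q <= alpha, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        repetition = rep_i, seed = seed_i, method = m,
        n_common_genes = length(genes), n_significant = n_sig,
        proportion_significant = n_sig / length(genes),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reproducibility of gene rankings across resampled datasets
#'
#' Generates `n_rep_per_arm` balanced datasets (random subsets of replicates,
#' at least `min_reps` per condition) and the same number of imbalanced
#' datasets (a replicate subset followed by even-interval 0.20-1 cell
#' subsampling), runs each method on every dataset, and returns Spearman's
#' rank correlation of the nominal p-value vectors for every unordered pair
#' of datasets (pairwise-complete over shared tested genes). Methods whose
#' p-values are constant on a dataset yield NA for that dataset's pairs.
#'
#' @param data a two-condition [cell_counts()] with at least `min_reps + 1`
#'   replicates per condition.
#' @param methods character vector of method names.
#' @param n_rep_per_arm datasets per arm (default 50, so 100 in total).
#' @param min_reps minimum replicates retained per condition (default 4).
#' @param master_seed integer master seed.
#' @param min_prop,max_prop retention range of the imbalanced arm.
#' @return A list with `pairs` (data.frame: `method`, `dataset_i`,
#'   `dataset_j`, `balanced_i`, `balanced_j`, `spearman_rho`) and `datasets`
#'   (data.frame describing the 2 x `n_rep_per_arm` generated datasets).
#' @export
reproducibility <- function(data, methods, n_rep_per_arm = 50, min_reps = 4,
                            master_seed = 1L, min_prop = 0.2, max_prop = 1) {
  stopifnot(inherits(data, "cell_counts"))
  cond <- data$sample_condition
  by_cond <- split(names(cond), unname(cond))
  if (length(by_cond) != 2) stop("need exactly two conditions")
  avail <- vapply(by_cond, length, integer(1))
  if (any(avail < min_reps + 1)) {
    stop("need at least min_reps + 1 replicates per condition")
  }
  n_total <- 2 * n_rep_per_arm
  meta <- data.frame(dataset = seq_len(n_total),
                     balanced = rep(c(TRUE, FALSE), each = n_rep_per_arm),
                     seed = NA_integer_)
  pmats <- stats::setNames(
    lapply(methods, function(m) matrix(NA_real_, nrow(data$counts), n_total,
                                       dimnames = list(data$gene_ids, NULL))),
    methods)
  for (d in seq_len(n_total)) {
    seed_d <- derive_seed(master_seed, d)
    meta$seed[d] <- seed_d
    set.seed(seed_d)
    keep_samples <- unlist(lapply(by_cond, function(s) {
      k <- sample(seq(min_reps, length(s) - 1), 1)
      sample(s, k)
    }), use.names = FALSE)
    sub <- subset_cells(
      data, cells = which(as.character(data$cell_sample) %in% keep_samples))
    if (!meta$balanced[d]) {
      sub <- subsample_imbalance(sub, min_prop, max_prop,
                                 seed = derive_seed(seed_d, 2))
    }
    for (m in methods) {
      res <- tryCatch(
        run_ds_method(sub, m, seed = derive_seed(seed_d, 3)),
        error = function(e) NULL)
      if (!is.null(res)) {
        pmats[[m]][match(res$gene_id, data$gene_ids), d] <- res$p_value
      }
    }
  }
  pair_idx <- utils::combn(n_total, 2)
  rows <- lapply(methods, function(m) {
    cmat <- suppressWarnings(
      stats::cor(pmats[[m]], method = "spearman",
                 use = "pairwise.complete.obs"))
    data.frame(
      method = m,
      dataset_i = pair_idx[1, ],
      dataset_j = pair_idx[2, ],
      balanced_i = meta$balanced[pair_idx[1, ]],
      balanced_j = meta$balanced[pair_idx[2, ]],
      spearman_rho = cmat[cbind(pair_idx[1, ], pair_idx[2, ])],
      stringsAsFactors = FALSE)
  })
  list(pairs = do.call(rbind, rows), datasets = meta)
}

#' Profile discordant calls: overlap, fold change and expression by class
#'
#' Partitions each method's evaluated genes into TP/FP/TN/FN at BH `alpha`
#' and reports, per gene: (a) the average overlap of pseudobulk values
#' between the two condition groups, (b) the absolute pseudocount log2 fold
#' change of pseudobulk means, (c) mean pseudobulk expression and (d) mean
#' single-cell normalized expression.
#'
#' @param results list of [ds_result()] objects.
#' @param truth truth data.frame (`gene_id`, `is_ds`).
#' @param pb a normalized `pseudobulk` object for the same genes.
#' @param normalized genes x cells single-cell normalized matrix.
#' @param alpha FDR cutoff.
#' @return Long data.frame: `method`, `gene_id`, `class`, `avg_overlap`,
#'   `abs_log2fc`, `mean_pb`, `mean_sc`.
#' @export
discordance_profile <- function(results, truth, pb, normalized, alpha = 0.05) {
  stopifnot(inherits(pb, "pseudobulk"))
  genes <- common_genes(results)
  cond <- pb$sample_condition
  lv <- unique(unname(cond))
  in_a <- cond == lv[1]
  pbv <- pb$values[match(genes, rownames(pb$values)), , drop = FALSE]
  ov <- apply(pbv, 1, function(v) average_overlap(v[in_a], v[!in_a]))
  ma <- rowMeans(pbv[, in_a, drop = FALSE])
  mb <- rowMeans(pbv[, !in_a, drop = FALSE])
  abs_lfc <- abs(log2((ma + 1) / (mb + 1)))
  mean_pb <- rowMeans(pbv)
  mean_sc <- rowMeans(normalized[match(genes, rownames(normalized)), ,
                                 drop = FALSE])
  is_ds <- truth$is_ds[match(genes, truth$gene_id)]
  out <- lapply(results, function(r) {
    p <- r$p_value[match(genes, r$gene_id)]
    q <- bh_adjust(p)
    pos <- q <= alpha
    cls <- ifelse(pos & is_ds, "TP",
           ifelse(pos & !is_ds, "FP",
           ifelse(!pos & is_ds, "FN", "TN")))
    data.frame(method = attr(r, "method"), gene_id = genes, class = cls,
               avg_overlap = ov, abs_log2fc = abs_lfc,
               mean_pb = mean_pb, mean_sc = mean_sc,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
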