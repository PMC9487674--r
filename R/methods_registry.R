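#' Available differential-state methods
#'
#' Names accepted by [run_ds_method()] and the protocol functions, spanning
#' the four families compared in the benchmark: naive single-cell tests,
#' latent-variable variants (subject identity as fixed-effect covariates), a
#' subject-random-intercept mixed model, and pseudobulk tests on sum or mean
#' aggregates.
#'
#' @return Character vector of method names.
#' @export
ds_methods <- function() {
  c("wilcoxon", "lr", "lr_latent", "poisson", "poisson_latent",
    "negbinom", "negbinom_latent", "hurdle", "hurdle_latent",
    "lmm",
    "pb_modt_sum", "pb_modt_mean", "pb_nbglm_tmm", "pb_nbglm_mor",
    "pb_rots_sum", "pb_rots_mean")
}

# Table-1-style filtering rule per method
.method_filter <- function(method) {
  switch(method,
    poisson = , poisson_latent = , negbinom = , negbinom_latent =
      list(rule = "min_cells_expressing", k = 3),
    lmm = list(rule = "min_cells_expressing_and_min_cells_per_sample",
               k = 20, m = 10),
    list(rule = "nonexpressed")
  )
}

#' Run one differential-state method on a dataset
#'
#' Applies the method's gene filter, its normalization/aggregation, and its
#' statistical test, then maps the result back to the full input gene set
#' (untested genes get NA p-values and `tested = FALSE`).
#'
#' @param data a [cell_counts()] object with two conditions.
#' @param method a name from [ds_methods()].
#' @param groups optional condition label per sample (named character);
#'   defaults to the dataset's own condition map. Used by the mock protocol
#'   to impose artificial splits.
#' @param seed integer seed for stochastic methods (the ROTS-style test).
#' @param ... extra arguments passed to the underlying test.
#' @return A [ds_result()] over all genes of `data`.
#' @export
run_ds_method <- function(data, method, groups = NULL, seed = 1L, ...) {
  stopifnot(inherits(data, "cell_counts"))
  method <- match.arg(method, ds_methods())
  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("groups must be named by sample id")
    data <- cell_counts(data$counts, as.character(data$cell_sample),
                        groups[names(data$sample_condition)],
                        gene_ids = data$gene_ids, cell_ids = data$cell_ids)
  }
  filt <- .method_filter(method)
  fd <- apply_gene_filter(data, rule = filt$rule, k = filt$k, m = filt$m)
  d <- fd$data
  cond <- factor(cell_condition(d))
  subj <- d$cell_sample
  res <- switch(method,
    wilcoxon = wilcoxon_test(lognormalize(d), cond),
    lr = lr_test(lognormalize(d), cond),
    lr_latent = lr_test(lognormalize(d), cond, latent = subj),
    poisson = poisson_glm_test(d$counts, cond),
    poisson_latent = poisson_glm_test(d$counts, cond, latent = subj),
    negbinom = negbinom_glm_test(d$counts, cond),
    negbinom_latent = negbinom_glm_test(d$counts, cond, latent = subj),
    hurdle = hurdle_test(lognormalize(d), cond),
    hurdle_latent = hurdle_test(lognormalize(d), cond, latent = subj),
    lmm = lmm_random_intercept_test(lognormalize(d), cond, subj),
    pb_modt_sum = pb_moderated_t(cpm_log2(aggregate_sum(d))),
    pb_modt_mean = pb_moderated_t(aggregate_mean(lognormalize(d), d)),
    pb_nbglm_tmm = pb_nbglm(aggregate_sum(d), norm = "tmm", ...),
    pb_nbglm_mor = pb_nbglm(aggregate_sum(d), norm = "median_of_ratios", ...),
    pb_rots_sum = pb_rots(cpm_log2(aggregate_sum(d)), seed = seed, ...),
    pb_rots_mean = pb_rots(aggregate_mean(lognormalize(d), d), seed = seed, ...)
  )
  attr(res, "method") <- method
  .expand_result(res, data$gene_ids)
}
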