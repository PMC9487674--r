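#' Genes tested by every method
#'
#' The benchmark's reconciliation step: methods filter genes differently, so
#' evaluation (and multiple-testing adjustment) is restricted to the
#' intersection of the tested-gene masks, with untested-NA genes excluded.
#'
#' @param results list of [ds_result()] objects on the same gene universe.
#' @return Character vector of gene ids tested (with a p-value) by all
#'   methods.
#' @export
common_genes <- function(results) {
  if (!length(results)) stop("need at least one result")
  masks <- lapply(results, function(r) r$gene_id[r$tested & !is.na(r$p_value)])
  out <- Reduce(intersect, masks)
  if (!length(out)) stop("no gene tested by all methods")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; NA entries are passed through untouched and do not
#' count towards the number of tests.
#'
#' @param p numeric p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve with p-values as the predictor
#'
#' Rank-based AUROC using score = -p with midranks for ties: the probability
#' that a randomly chosen truly-DS gene receives a smaller p-value than a
#' randomly chosen non-DS gene (ties counting 1/2).
#'
#' @param p per-gene p-values (smaller = more confident call).
#' @param truth logical, TRUE for genes with a true differential state.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(p, truth) {
  ok <- !is.na(p) & !is.na(truth)
  p <- p[ok]; truth <- as.logical(truth[ok])
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(-p)          # large rank = small p = confident
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at an FDR cutoff
#'
#' Genes with adjusted p-value <= `alpha` are called positive. Sensitivity,
#' specificity, precision, F1 and Matthews correlation coefficient follow
#' their standard definitions; precision and F1 are NA (undefined, not zero)
#' when no positives are called, and MCC is NA when any marginal of the
#' confusion matrix is zero.
#'
#' @param q adjusted p-values (e.g. from [bh_adjust()]).
#' @param truth logical ground-truth DS indicator, aligned with `q`.
#' @param alpha FDR cutoff, default 0.05.
#' @return Named list: tp, fp, tn, fn, sensitivity, specificity, precision,
#'   f1, mcc, n_genes_evaluated, n_significant.
#' @export
confusion_metrics <- function(q, truth, alpha = 0.05) {
  ok <- !is.na(q) & !is.na(truth)
  q <- q[ok]; truth <- as.logical(truth[ok])
  pos <- q <= alpha
  tp <- sum(pos & truth); fp <- sum(pos & !truth)
  fn <- sum(!pos & truth); tn <- sum(!pos & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, mcc = mcc,
       n_genes_evaluated = length(q), n_significant = sum(pos))
}

#' Average overlap of two groups of replicate values
#'
#' For replicate vectors x_A (length m) and x_B (length n), counts
#' m' = how many x_A values lie within \[min(x_B), max(x_B)\] and
#' n' = how many x_B values lie within \[min(x_A), max(x_A)\], and returns
#' O = (m'/m + n'/n) / 2. Values near 1 indicate indistinguishable groups,
#' values near 0 separated groups.
#'
#' @param x_a,x_b numeric vectors of per-replicate (pseudobulk) values.
#' @return O in \[0, 1\].
#' @export
average_overlap <- function(x_a, x_b) {
  if (!length(x_a) || !length(x_b)) stop("both groups need >= 1 value")
  m_prime <- sum(x_a >= min(x_b) & x_a <= max(x_b))
  n_prime <- sum(x_b >= min(x_a) & x_b <= max(x_a))
  (m_prime / length(x_a) + n_prime / length(x_b)) / 2
}

#' Evaluate one method's result against simulation truth
#'
#' Restricts to `genes` (typically [common_genes()] output), BH-adjusts the
#' p-values, and computes AUROC plus the confusion metrics at `alpha`.
#'
#' @param result a [ds_result()].
#' @param truth truth data.frame with `gene_id` and `is_ds`.
#' @param genes gene ids to evaluate on; default all tested genes.
#' @param alpha FDR cutoff.
#' @param dataset_id identifier stored in the output row.
#' @return One-row data.frame (an EvalSummary record).
#' @export
evaluate_result <- function(result, truth, genes = NULL, alpha = 0.05,
                            dataset_id = NA_character_) {
  if (is.null(genes)) {
    genes <- result$gene_id[result$tested & !is.na(result$p_value)]
  }
  idx <- match(genes, result$gene_id)
  p <- result$p_value[idx]
  is_ds <- truth$is_ds[match(genes, truth$gene_id)]
  q <- bh_adjust(p)
  auc <- if (length(unique(is_ds)) == 2) auroc(p, is_ds) else NA_real_
  cm <- confusion_metrics(q, is_ds, alpha = alpha)
  data.frame(
    method = attr(result, "method"),
    dataset_id = dataset_id,
    auroc = auc,
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    precision = cm$precision,
    f1 = cm$f1,
    mcc = cm$mcc,
    n_genes_evaluated = cm$n_genes_evaluated,
    n_significant = cm$n_significant,
    stringsAsFactors = FALSE
  )
}
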