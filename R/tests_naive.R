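#' Wilcoxon rank-sum test per gene
#'
#' The naive two-group test applied to every gene of a normalized cell-level
#' matrix, treating all cells as independent. Two-sided p-values use the
#' normal approximation with tie correction and continuity correction. The
#' effect is the Seurat-style log2 fold change of de-logged group means:
#' `log2((mean(expm1(x_A)) + 1) / (mean(expm1(x_B)) + 1))` with condition A
#' the first factor level.
#'
#' @param normalized genes x cells matrix of log-normalized values.
#' @param groups two-level factor of length `ncol(normalized)`.
#' @return A [ds_result()].
#' @export
wilcoxon_test <- function(normalized, groups) {
  groups <- .two_groups(groups, ncol(normalized))
  in_a <- groups == levels(groups)[1]
  n1 <- sum(in_a); n2 <- sum(!in_a); n <- n1 + n2
  p <- apply(normalized, 1, .rank_sum_p, in_a = in_a, n1 = n1, n2 = n2, n = n)
  eff <- .log2fc_expm1(normalized, in_a)
  ds_result(rownames(normalized), p, eff, rep(TRUE, nrow(normalized)),
            "wilcoxon", list(family = "naive"))
}

# normal-approximation rank-sum p with tie and continuity corrections
.rank_sum_p <- function(x, in_a, n1, n2, n) {
  r <- rank(x)
  u <- sum(r[in_a]) - n1 * (n1 + 1) / 2
  ties <- rle(sort(x))$lengths
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

.log2fc_expm1 <- function(normalized, in_a, pseudo = 1) {
  ma <- rowMeans(expm1(normalized[, in_a, drop = FALSE]))
  mb <- rowMeans(expm1(normalized[, !in_a, drop = FALSE]))
  log2((ma + pseudo) / (mb + pseudo))
}

# build a latent-covariate model matrix (subject dummies); drops columns that
# would make the design singular given the intercept
.latent_matrix <- function(latent, n) {
  if (is.null(latent)) return(NULL)
  if (is.vector(latent) || is.factor(latent)) {
    latent <- stats::model.matrix(~ factor(latent))[, -1, drop = FALSE]
  }
  if (nrow(latent) != n) stop("latent covariates misaligned with cells")
  latent
}

#' Logistic-regression membership test per gene
#'
#' For each gene, group membership is regressed on the gene's normalized
#' expression (plus any latent covariates); significance is the
#' likelihood-ratio test (df 1) of the model with the gene term against the
#' model without it. With subject identities supplied as latent covariates
#' this is the latent-variable variant.
#'
#' @inheritParams wilcoxon_test
#' @param latent optional vector/factor (e.g. subject ids) or numeric matrix
#'   of cell-level covariates included in both models.
#' @return A [ds_result()]; genes whose fits fail to converge get NA p-values.
#' @export
lr_test <- function(normalized, groups, latent = NULL) {
  groups <- .two_groups(groups, ncol(normalized))
  y <- as.integer(groups == levels(groups)[2])
  lm_lat <- .latent_matrix(latent, ncol(normalized))
  null_dev <- suppressWarnings(if (is.null(lm_lat)) {
    stats::glm(y ~ 1, family = stats::binomial())$deviance
  } else {
    stats::glm(y ~ lm_lat, family = stats::binomial())$deviance
  })
  p <- apply(normalized, 1, function(x) {
    # non-convergence from complete separation still yields a valid deviance
    # limit (the LRT statistic tends to 0 when the covariates already separate
    # the groups), so only hard errors produce a missing p-value
    fit <- tryCatch(suppressWarnings(
      if (is.null(lm_lat)) stats::glm(y ~ x, family = stats::binomial())
      else stats::glm(y ~ x + lm_lat, family = stats::binomial())
    ), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    stat <- max(0, null_dev - fit$deviance)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  })
  in_a <- groups == levels(groups)[1]
  eff <- .log2fc_expm1(normalized, in_a)
  ds_result(rownames(normalized), p, eff, rep(TRUE, nrow(normalized)),
            if (is.null(latent)) "lr" else "lr_latent",
            list(family = if (is.null(latent)) "naive" else "latent"))
}

#' Poisson GLM test per gene
#'
#' Per-gene Poisson regression of raw counts on condition (plus latent
#' covariates) with a log library-size offset; p from the likelihood-ratio
#' test of the condition term.
#'
#' @param counts genes x cells raw count matrix.
#' @param groups two-level factor over cells.
#' @param lib_sizes per-cell library sizes; default column sums of `counts`.
#' @inheritParams lr_test
#' @return A [ds_result()] with effects on the log2 scale.
#' @export
poisson_glm_test <- function(counts, groups, latent = NULL,
                             lib_sizes = colSums(counts)) {
  .count_glm_test(counts, groups, latent, lib_sizes, negbin = FALSE)
}

#' Negative-binomial GLM test per gene
#'
#' As [poisson_glm_test()] but with a per-gene NB dispersion estimated by
#' maximum likelihood (method-of-moments start, via [MASS::glm.nb()]). Genes
#' whose dispersion collapses to zero (or whose NB fit fails) fall back to the
#' Poisson model.
#'
#' @inheritParams poisson_glm_test
#' @return A [ds_result()].
#' @export
negbinom_glm_test <- function(counts, groups, latent = NULL,
                              lib_sizes = colSums(counts)) {
  .count_glm_test(counts, groups, latent, lib_sizes, negbin = TRUE)
}

.count_glm_test <- function(counts, groups, latent, lib_sizes, negbin) {
  groups <- .two_groups(groups, ncol(counts))
  g <- as.integer(groups == levels(groups)[2])
  off <- log(lib_sizes)
  lm_lat <- .latent_matrix(latent, ncol(counts))
  res <- apply(counts, 1, function(y) {
    .one_count_glm(y, g, lm_lat, off, negbin)
  })
  p <- res[1, ]
  eff <- res[2, ] / log(2)
  base <- if (negbin) "negbinom" else "poisson"
  params <- list(family = if (is.null(latent)) "naive" else "latent")
  if (negbin) params$dispersion <- unname(res[3, ])
  ds_result(rownames(counts), p, eff, rep(TRUE, nrow(counts)),
            if (is.null(latent)) base else paste0(base, "_latent"),
            params)
}

# one gene: LRT p, natural-log group coefficient, dispersion (1/theta; 0 for
# the Poisson model)
.one_count_glm <- function(y, g, lm_lat, off, negbin) {
  form_full <- if (is.null(lm_lat)) y ~ g else y ~ g + lm_lat
  form_null <- if (is.null(lm_lat)) y ~ 1 else y ~ lm_lat
  pois <- function() {
    full <- suppressWarnings(stats::glm(form_full, family = stats::poisson(),
                                        offset = off))
    null <- suppressWarnings(stats::glm(form_null, family = stats::poisson(),
                                        offset = off))
    stat <- max(0, null$deviance - full$deviance)
    c(stats::pchisq(stat, 1, lower.tail = FALSE),
      unname(stats::coef(full)["g"]), 0)
  }
  out <- tryCatch({
    if (negbin) {
      full <- suppressWarnings(MASS::glm.nb(
        if (is.null(lm_lat)) y ~ g + offset(off) else y ~ g + lm_lat + offset(off)))
      null <- suppressWarnings(MASS::glm.nb(
        if (is.null(lm_lat)) y ~ offset(off) else y ~ lm_lat + offset(off),
        init.theta = full$theta))
      stat <- max(0, 2 * (stats::logLik(full) - stats::logLik(null)))
      c(stats::pchisq(stat, 1, lower.tail = FALSE),
        unname(stats::coef(full)["g"]), 1 / full$theta)
    } else {
      pois()
    }
  }, error = function(e) NULL)
  if (is.null(out) && negbin) {
    # NB fit failed (often dispersion -> 0): Poisson fallback
    out <- tryCatch(pois(), error = function(e) NULL)
  }
  if (is.null(out)) c(NA_real_, NA_real_, NA_real_) else out
}

#' Two-part hurdle test per gene
#'
#' A hurdle model on log-normalized expression: a logistic regression on
#' detection (value > 0) and a Gaussian linear model on the positive values,
#' each with the condition term (plus latent covariates). The two
#' likelihood-ratio chi-square statistics on the condition term are summed,
#' degrees of freedom are summed, and one combined p-value is returned. When
#' either group has fewer than 2 detected cells the continuous part is
#' dropped; all-zero genes get NA.
#'
#' @inheritParams lr_test
#' @return A [ds_result()].
#' @export
hurdle_test <- function(normalized, groups, latent = NULL) {
  groups <- .two_groups(groups, ncol(normalized))
  g <- as.integer(groups == levels(groups)[2])
  lm_lat <- .latent_matrix(latent, ncol(normalized))
  p <- apply(normalized, 1, .one_hurdle, g = g, lm_lat = lm_lat)
  in_a <- groups == levels(groups)[1]
  eff <- .log2fc_expm1(normalized, in_a)
  ds_result(rownames(normalized), p, eff, rep(TRUE, nrow(normalized)),
            if (is.null(latent)) "hurdle" else "hurdle_latent",
            list(family = if (is.null(latent)) "naive" else "latent"))
}

.one_hurdle <- function(x, g, lm_lat) {
  det <- as.integer(x > 0)
  if (all(det == 0)) return(NA_real_)
  stat <- 0; df <- 0
  # discrete part (skipped if detection is constant: no information)
  if (stats::var(det) > 0) {
    d <- tryCatch({
      full <- suppressWarnings(
        if (is.null(lm_lat)) stats::glm(det ~ g, family = stats::binomial())
        else stats::glm(det ~ g + lm_lat, family = stats::binomial()))
      null <- suppressWarnings(
        if (is.null(lm_lat)) stats::glm(det ~ 1, family = stats::binomial())
        else stats::glm(det ~ lm_lat, family = stats::binomial()))
      max(0, null$deviance - full$deviance)
    }, error = function(e) NA_real_)
    if (!is.na(d)) { stat <- stat + d; df <- df + 1 }
  }
  # continuous part on detected cells
  pos <- det == 1
  if (sum(pos & g == 0) >= 2 && sum(pos & g == 1) >= 2) {
    xc <- x[pos]; gc <- g[pos]
    latc <- if (is.null(lm_lat)) NULL else lm_lat[pos, , drop = FALSE]
    c2 <- tryCatch({
      full <- if (is.null(latc)) stats::lm(xc ~ gc) else stats::lm(xc ~ gc + latc)
      null <- if (is.null(latc)) stats::lm(xc ~ 1) else stats::lm(xc ~ latc)
      rss1 <- sum(stats::residuals(full)^2)
      rss0 <- sum(stats::residuals(null)^2)
      if (rss1 <= 0) NA_real_ else length(xc) * log(rss0 / rss1)
    }, error = function(e) NA_real_)
    if (!is.na(c2)) { stat <- stat + c2; df <- df + 1 }
  }
  if (df == 0) return(NA_real_)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}
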