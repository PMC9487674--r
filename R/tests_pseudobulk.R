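#' Moderated t-test on pseudobulk values
#'
#' Gene-wise two-group linear model with empirical-Bayes variance shrinkage.
#' Residual variances s2_g with d_g degrees of freedom are shrunk towards a
#' common prior: the posterior variance is
#' `(d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`, with the prior degrees of freedom
#' d0 and prior variance s0^2 estimated by moment matching of log s2_g against
#' the scaled-F law (digamma/trigamma moments; d0 solved by a Newton inversion
#' of the trigamma function). The moderated t has `d_g + d0` degrees of
#' freedom.
#'
#' @param pb a `pseudobulk` object on a log scale (sum aggregation with
#'   TMM+CPM+log2 values, or mean aggregation of log-normalized values).
#' @param groups optional two-level factor over samples; defaults to the
#'   pseudobulk's condition map.
#' @return A [ds_result()] with `params` carrying `d0` and `s0_2`.
#' @export
pb_moderated_t <- function(pb, groups = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  x <- pb$values
  if (is.null(groups)) groups <- pb$sample_condition[colnames(x)]
  groups <- .two_groups(groups, ncol(x))
  if (ncol(x) < 3) stop("need at least 3 samples in total")
  in_a <- groups == levels(groups)[1]
  n1 <- sum(in_a); n2 <- sum(!in_a)
  m1 <- rowMeans(x[, in_a, drop = FALSE])
  m2 <- rowMeans(x[, !in_a, drop = FALSE])
  rss <- rowSums((x[, in_a, drop = FALSE] - m1)^2) +
         rowSums((x[, !in_a, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- rss / dg
  prior <- .fit_f_dist(s2, dg)
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (prior$d0 * prior$s0_2 + dg * s2) / (prior$d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  df_total <- dg + prior$d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0] <- ifelse(m2[se == 0] == m1[se == 0], 1, 0)
  ds_result(rownames(x), p, m2 - m1, rep(TRUE, nrow(x)),
            "pb_moderated_t",
            list(family = "pseudobulk", aggregation = pb$aggregation,
                 normalization = pb$normalization,
                 d0 = prior$d0, s0_2 = prior$s0_2))
}

# moment-matching fit of the scaled-F prior on sample variances.
# z = log(s2) has E[z] = log(s0^2) + digamma(d0/2) - log(d0/2)
#                        + digamma(dg/2) - log(dg/2)
# and Var[z] = trigamma(dg/2) + trigamma(d0/2).
.fit_f_dist <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_2 = stats::median(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e)
  resid_var <- evar - trigamma(dg / 2)
  if (resid_var <= 0) {
    # sample variances are less dispersed than chi-square: infinite prior df
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(resid_var)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(y) = x for y > 0
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Negative-binomial GLM on summed pseudobulk counts
#'
#' Per-gene NB regression of summed counts on condition with normalization
#' offsets from TMM effective library sizes or median-of-ratios size factors.
#' The per-gene dispersion is a weighted average of the gene's
#' method-of-moments estimate and a lowess trend of those estimates over mean
#' abundance, with prior weight equivalent to 10 samples. Significance is a
#' Wald test on the condition coefficient.
#'
#' @param pb a sum-aggregated raw `pseudobulk` object.
#' @param groups optional two-level factor over samples.
#' @param norm `"tmm"` (offset = log of TMM effective library size) or
#'   `"median_of_ratios"` (offset = log size factor).
#' @param dispersion optional fixed dispersion (scalar or per-gene vector)
#'   overriding estimation; 0 selects the Poisson model.
#' @param prior_weight weight (in samples) of the trended dispersion.
#' @return A [ds_result()]; all-zero genes get NA p-values.
#' @export
pb_nbglm <- function(pb, groups = NULL, norm = c("tmm", "median_of_ratios"),
                     dispersion = NULL, prior_weight = 10) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (pb$aggregation != "sum" || pb$normalization != "raw") {
    stop("pb_nbglm expects raw, sum-aggregated pseudobulk counts")
  }
  norm <- match.arg(norm)
  x <- pb$values
  if (is.null(groups)) groups <- pb$sample_condition[colnames(x)]
  groups <- .two_groups(groups, ncol(x))
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  off <- if (norm == "tmm") {
    log(colSums(x) * tmm_factors(pb))
  } else {
    log(median_of_ratios_factors(pb))
  }
  g <- as.integer(groups == levels(groups)[2])
  sf <- exp(off - mean(off))
  qn <- sweep(x, 2, sf, "/")           # normalized counts for dispersion
  if (is.null(dispersion)) {
    dispersion <- .trended_dispersion(qn, groups, prior_weight)
  } else if (length(dispersion) == 1) {
    dispersion <- rep(dispersion, nrow(x))
  }
  res <- vapply(seq_len(nrow(x)), function(i) {
    y <- x[i, ]
    if (all(y == 0)) return(c(NA_real_, NA_real_))
    fam <- if (dispersion[i] <= 1e-8) stats::poisson() else
      MASS::negative.binomial(theta = 1 / dispersion[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ g, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    # scale fixed at 1: overdispersion already lives in the NB variance
    cf <- summary(fit, dispersion = 1)$coefficients
    if (!"g" %in% rownames(cf)) return(c(NA_real_, NA_real_))
    z <- cf["g", "Estimate"] / cf["g", "Std. Error"]
    c(2 * stats::pnorm(-abs(z)), cf["g", "Estimate"] / log(2))
  }, numeric(2))
  ds_result(rownames(x), res[1, ], res[2, ], !is.na(res[1, ]),
            "pb_nbglm", list(family = "pseudobulk", normalization = norm,
                             dispersion = dispersion))
}

# method-of-moments gene dispersions shrunk to a lowess abundance trend
.trended_dispersion <- function(qn, groups, prior_weight) {
  n <- ncol(qn)
  mu <- rowMeans(qn)
  in_a <- groups == levels(groups)[1]
  # within-group pooled variance so true fold changes do not inflate it
  v <- (rowSums((qn[, in_a, drop = FALSE] - rowMeans(qn[, in_a, drop = FALSE]))^2) +
        rowSums((qn[, !in_a, drop = FALSE] - rowMeans(qn[, !in_a, drop = FALSE]))^2)) /
       (n - 2)
  mom <- pmax((v - mu) / mu^2, 0)
  mom[!is.finite(mom)] <- 0
  ok <- mu > 0
  trend <- rep(stats::median(mom[ok]), length(mom))
  if (sum(ok) >= 10) {
    lo <- stats::lowess(log(mu[ok]), mom[ok], f = 0.5)
    trend[ok] <- pmax(stats::approx(lo$x, lo$y, xout = log(mu[ok]),
                                    rule = 2)$y, 0)
  }
  pmax((n * mom + prior_weight * trend) / (n + prior_weight), 1e-8)
}

#' Reproducibility-optimized test statistic on pseudobulk values
#'
#' Ranks genes by the statistic `d_g = |mean_A - mean_B| / (a1 + a2 * s_g)`,
#' where s_g is the pooled standard error of the mean difference. The pair
#' (a1, a2) and the top-list size k are selected from a fixed grid by
#' maximizing the reproducibility Z-score: bootstrap pairs of datasets
#' (samples resampled within groups) are compared through the overlap of
#' their top-k gene lists, against the same overlap under permuted group
#' labels. P-values come from pooled permutations of the selected statistic.
#'
#' @param pb a log-scale `pseudobulk` object (>= 3 samples per group).
#' @param groups optional two-level factor over samples.
#' @param n_bootstrap number of bootstrap (and permutation) pairs.
#' @param toplist_sizes candidate top-list sizes; defaults to
#'   `c(5, 10, 25, 50)` capped at half the gene count.
#' @param a1_grid,a2_grid regularization grid; (0, 0) is excluded.
#' @param n_perm_p permutations for the pooled p-value null.
#' @param seed integer RNG seed.
#' @return A [ds_result()] with `params` carrying the selected `a1`, `a2`,
#'   `k` and the statistic vector `d`.
#' @export
pb_rots <- function(pb, groups = NULL, n_bootstrap = 100,
                    toplist_sizes = NULL,
                    a1_grid = c(0, 0.01, 0.1, 0.25, 0.5, 1),
                    a2_grid = c(0, 1), n_perm_p = 100, seed = 1L) {
  stopifnot(inherits(pb, "pseudobulk"))
  x <- pb$values
  if (is.null(groups)) groups <- pb$sample_condition[colnames(x)]
  groups <- .two_groups(groups, ncol(x))
  if (any(table(groups) < 3)) stop("need >= 3 samples per group")
  set.seed(seed)
  G <- nrow(x)
  if (is.null(toplist_sizes)) {
    toplist_sizes <- unique(pmin(c(5, 10, 25, 50), max(1, floor(G / 2))))
  }
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  grid <- expand.grid(a1 = a1_grid, a2 = a2_grid)
  grid <- grid[!(grid$a1 == 0 & grid$a2 == 0), , drop = FALSE]

  boot_pair <- function(cols_a, cols_b) {
    lapply(seq_len(nrow(grid)),
           function(j) .rots_stat(x, cols_a, cols_b, grid$a1[j], grid$a2[j]))
  }
  resample <- function(idx) idx[sample.int(length(idx), replace = TRUE)]

  overlaps_obs <- array(NA_real_, c(n_bootstrap, nrow(grid), length(toplist_sizes)))
  overlaps_null <- overlaps_obs
  for (b in seq_len(n_bootstrap)) {
    d1 <- boot_pair(resample(ia), resample(ib))
    d2 <- boot_pair(resample(ia), resample(ib))
    perm <- sample(c(ia, ib))
    pa <- perm[seq_along(ia)]; pbx <- perm[-seq_along(ia)]
    d1n <- boot_pair(resample(pa), resample(pbx))
    d2n <- boot_pair(resample(pa), resample(pbx))
    for (j in seq_len(nrow(grid))) {
      for (ki in seq_along(toplist_sizes)) {
        k <- toplist_sizes[ki]
        overlaps_obs[b, j, ki] <- .top_overlap(d1[[j]], d2[[j]], k)
        overlaps_null[b, j, ki] <- .top_overlap(d1n[[j]], d2n[[j]], k)
      }
    }
  }
  zbest <- -Inf; best <- c(1, 1)
  for (j in seq_len(nrow(grid))) {
    for (ki in seq_along(toplist_sizes)) {
      sdv <- stats::sd(overlaps_obs[, j, ki])
      z <- (mean(overlaps_obs[, j, ki]) - mean(overlaps_null[, j, ki])) /
           (if (is.na(sdv) || sdv < 1e-12) 1e-12 else sdv)
      if (z > zbest) { zbest <- z; best <- c(j, ki) }
    }
  }
  a1 <- grid$a1[best[1]]; a2 <- grid$a2[best[1]]
  k_sel <- toplist_sizes[best[2]]
  d_obs <- .rots_stat(x, ia, ib, a1, a2)

  # pooled permutation null for the selected statistic
  null_pool <- numeric(0)
  for (r in seq_len(n_perm_p)) {
    perm <- sample(c(ia, ib))
    null_pool <- c(null_pool,
                   .rots_stat(x, perm[seq_along(ia)], perm[-seq_along(ia)],
                              a1, a2))
  }
  null_sorted <- sort(null_pool)
  n_null <- length(null_sorted)
  ge <- n_null - findInterval(d_obs - 1e-12, null_sorted)
  p <- (1 + ge) / (1 + n_null)
  in_a <- seq_len(ncol(x)) %in% ia
  eff <- rowMeans(x[, !in_a, drop = FALSE]) - rowMeans(x[, in_a, drop = FALSE])
  ds_result(rownames(x), p, eff, rep(TRUE, G), "pb_rots",
            list(family = "pseudobulk", aggregation = pb$aggregation,
                 a1 = a1, a2 = a2, k = k_sel, z = zbest, d = d_obs))
}

# the regularized difference statistic on columns cols_a vs cols_b
.rots_stat <- function(x, cols_a, cols_b, a1, a2) {
  n1 <- length(cols_a); n2 <- length(cols_b)
  m1 <- rowMeans(x[, cols_a, drop = FALSE])
  m2 <- rowMeans(x[, cols_b, drop = FALSE])
  rss <- rowSums((x[, cols_a, drop = FALSE] - m1)^2) +
         rowSums((x[, cols_b, drop = FALSE] - m2)^2)
  s <- sqrt(rss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  abs(m1 - m2) / (a1 + a2 * s)
}

# fraction of shared genes among the top-k of two statistic vectors;
# ties broken stably by gene index
.top_overlap <- function(d1, d2, k) {
  t1 <- order(-d1, seq_along(d1))[seq_len(k)]
  t2 <- order(-d2, seq_along(d2))[seq_len(k)]
  length(intersect(t1, t2)) / k
}
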