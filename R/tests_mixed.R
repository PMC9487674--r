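#' Gaussian random-intercept mixed-model test per gene
#'
#' The mixed-model representative: for each gene a linear mixed model
#' `value ~ condition + (1 | subject)` is fitted, capturing between-subject
#' correlation of cells through a subject random intercept. Variance
#' components come from the (restricted-likelihood-based) `lme4` fit; the
#' condition p-value is a likelihood-ratio chi-square (df 1) comparing
#' maximum-likelihood fits with and without the condition term. Genes whose
#' subject variance collapses to zero (singular fit) fall back to the
#' ordinary least-squares F-test, which there coincides with the two-sample
#' t-test.
#'
#' @param normalized genes x cells matrix of log-normalized values.
#' @param groups two-level factor over cells (condition).
#' @param subjects vector/factor of subject ids per cell; each group needs at
#'   least 2 subjects.
#' @return A [ds_result()] whose `params` include per-gene variance-component
#'   estimates (`var_subject`, `var_residual` matrices of the REML fit).
#' @export
lmm_random_intercept_test <- function(normalized, groups, subjects) {
  groups <- .two_groups(groups, ncol(normalized))
  subjects <- factor(subjects)
  per_group <- tapply(as.character(subjects), groups,
                      function(s) length(unique(s)))
  if (any(per_group < 2)) stop("each group needs at least 2 subjects")
  g <- as.integer(groups == levels(groups)[2])
  G <- nrow(normalized)
  p <- numeric(G); vs <- numeric(G); vr <- numeric(G)
  for (i in seq_len(G)) {
    fit <- .one_lmm(normalized[i, ], g, subjects)
    p[i] <- fit[1]; vs[i] <- fit[2]; vr[i] <- fit[3]
  }
  in_a <- groups == levels(groups)[1]
  eff <- .log2fc_expm1(normalized, in_a)
  ds_result(rownames(normalized), p, eff, rep(TRUE, G),
            "lmm", list(family = "mixed", var_subject = vs, var_residual = vr))
}

.one_lmm <- function(x, g, subjects) {
  if (stats::var(x) == 0) return(c(1, 0, 0))
  df <- data.frame(x = x, g = g, subj = subjects)
  out <- tryCatch({
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    reml <- suppressMessages(suppressWarnings(
      lme4::lmer(x ~ g + (1 | subj), data = df, REML = TRUE, control = ctrl)))
    vc <- as.data.frame(lme4::VarCorr(reml))
    v_subj <- vc$vcov[vc$grp == "subj"]
    v_res <- vc$vcov[vc$grp == "Residual"]
    if (lme4::isSingular(reml, tol = 1e-5)) {
      c(.ols_p(x, g), v_subj, v_res)
    } else {
      full <- suppressMessages(suppressWarnings(
        lme4::lmer(x ~ g + (1 | subj), data = df, REML = FALSE, control = ctrl)))
      null <- suppressMessages(suppressWarnings(
        lme4::lmer(x ~ 1 + (1 | subj), data = df, REML = FALSE, control = ctrl)))
      stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                            as.numeric(stats::logLik(null))))
      c(stats::pchisq(stat, df = 1, lower.tail = FALSE), v_subj, v_res)
    }
  }, error = function(e) NULL)
  if (is.null(out)) c(.ols_p(x, g), NA_real_, NA_real_) else out
}

.ols_p <- function(x, g) {
  fit <- stats::lm(x ~ g)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2) return(1)
  cf["g", "Pr(>|t|)"]
}
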