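mk_mat <- function(x, ids = NULL) {
  m <- matrix(x, nrow = 1)
  rownames(m) <- if (is.null(ids)) "g1" else ids
  m
}

test_that("rank-sum p-values agree with exact enumeration and wilcox.test", {
  # complete separation, 3 vs 3: exact two-sided p = 2/20 = 0.1
  x <- mk_mat(c(1, 2, 3, 10, 11, 12))
  grp <- factor(rep(c("A", "B"), each = 3))
  expect_equal(exact_ranksum_p(x[1, ], grp == "A"), 0.1)
  res <- wilcoxon_test(x, grp)
  expect_lt(abs(res$p_value - 0.1), 0.03)  # normal approximation vs exact
  # identical groups
  same <- mk_mat(rep(c(1, 2, 3), 2))
  expect_equal(wilcoxon_test(same, grp)$p_value, 1, tolerance = 1e-6)
  # 20-cell toys with ties: match R's normal-approximation reference exactly
  set.seed(11)
  g20 <- factor(rep(c("A", "B"), each = 10))
  for (i in 1:5) {
    y <- mk_mat(rpois(20, 3))
    ref <- suppressWarnings(stats::wilcox.test(
      y[1, g20 == "A"], y[1, g20 == "B"], exact = FALSE,
      correct = TRUE))$p.value
    expect_equal(wilcoxon_test(y, g20)$p_value, ref, tolerance = 1e-10)
  }
  # continuous 20-cell toys: within 0.01 of the exact permutation law
  for (i in 1:5) {
    y <- mk_mat(rnorm(20) + 0.5 * (g20 == "B"))
    expect_lt(abs(wilcoxon_test(y, g20)$p_value -
                    exact_ranksum_p(y[1, ], g20 == "A")), 0.011)
  }
})

test_that("logistic-regression LRT matches an independent deviance computation", {
  set.seed(2)
  x <- mk_mat(c(rnorm(15, 0), rnorm(15, 1)))
  grp <- factor(rep(c("A", "B"), each = 15))
  res <- lr_test(x, grp)
  # independent route: optimize both binomial log-likelihoods numerically
  y <- as.integer(grp == "B")
  nll <- function(beta, with_x) {
    eta <- beta[1] + if (with_x) beta[2] * x[1, ] else 0
    -sum(y * eta - log1p(exp(eta)))
  }
  f1 <- stats::optim(c(0, 0), nll, with_x = TRUE, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500))
  # intercept-only binomial MLE is the group proportion, in closed form
  phat <- mean(y)
  nll0 <- -sum(y * log(phat) + (1 - y) * log(1 - phat))
  dev_diff <- 2 * (nll0 - f1$value)
  expect_equal(res$p_value,
               stats::pchisq(dev_diff, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # constant gene: statistic 0
  expect_equal(lr_test(mk_mat(rep(1, 30)), grp)$p_value, 1)
  # latent covariates that perfectly encode the groups leave nothing to test
  subj <- rep(paste0("s", 1:6), each = 5)
  res_lat <- lr_test(x, grp, latent = subj)
  expect_gt(res_lat$p_value, 0.9)
})

test_that("Poisson GLM deviance matches the closed form and respects offsets", {
  # 2 cells per group, equal depths: group MLEs are the group means
  y <- c(2, 4, 10, 14)
  x <- mk_mat(y)
  grp <- factor(rep(c("A", "B"), each = 2))
  lib <- rep(100, 4)
  res <- poisson_glm_test(x, grp, lib_sizes = lib)
  mu1 <- rep(mean(y[1:2]), 2); mu0 <- rep(mean(y), 4)
  dev_diff <- 2 * (sum(y * log(c(mu1, rep(mean(y[3:4]), 2))) -
                         c(mu1, rep(mean(y[3:4]), 2))) -
                   sum(y * log(mu0) - mu0))
  expect_equal(res$p_value, stats::pchisq(dev_diff, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # a common library-size rescale is absorbed by the intercept
  res2 <- poisson_glm_test(x, grp, lib_sizes = lib * 7)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-8)
  # equal group means, equal depths
  eq <- poisson_glm_test(mk_mat(c(5, 7, 5, 7)), grp, lib_sizes = lib)
  expect_gt(eq$p_value, 0.9)
})

test_that("NB GLM nests the Poisson and recovers a known dispersion", {
  set.seed(3)
  grp <- factor(rep(c("A", "B"), each = 100))
  # equidispersed: NB collapses to Poisson
  y_pois <- mk_mat(rpois(200, 5))
  lib <- rep(1000, 200)
  p_nb <- negbinom_glm_test(y_pois, grp, lib_sizes = lib)$p_value
  p_po <- poisson_glm_test(y_pois, grp, lib_sizes = lib)$p_value
  expect_lt(abs(p_nb - p_po), 0.01)
  # dispersion recovery at n = 2000 cells
  y_nb <- mk_mat(rnbinom(2000, mu = 8, size = 2))  # dispersion 0.5
  g2 <- factor(rep(c("A", "B"), each = 1000))
  res <- negbinom_glm_test(y_nb, g2, lib_sizes = rep(1000, 2000))
  disp_hat <- attr(res, "params")$dispersion[1]
  expect_gt(disp_hat, 0.25)
  expect_lt(disp_hat, 0.75)
  # equal groups
  expect_gt(negbinom_glm_test(mk_mat(rnbinom(200, mu = 5, size = 2)), grp,
                              lib_sizes = rep(500, 200))$p_value, 0.05)
})

test_that("hurdle combines detection and continuous parts correctly", {
  grp <- factor(rep(c("A", "B"), each = 40))
  set.seed(5)
  # identical groups: p near 1
  vals <- abs(rnorm(40, 2))
  x_same <- mk_mat(c(vals, vals))
  expect_gt(hurdle_test(x_same, grp)$p_value, 0.99)
  # detection-only difference: positives share one distribution, so the
  # combined p must match the discrete-part binomial LRT alone
  pos <- abs(rnorm(60, 2, 0.2)) + 1
  xa <- c(pos[1:10], rep(0, 30))          # 25% detected in A
  xb <- c(pos[11:45], rep(0, 5))          # 87.5% detected in B
  x_det <- mk_mat(c(xa, xb))
  res <- hurdle_test(x_det, grp)
  det <- as.integer(x_det[1, ] > 0)
  g <- as.integer(grp == "B")
  d_full <- stats::glm(det ~ g, family = binomial())$deviance
  d_null <- stats::glm(det ~ 1, family = binomial())$deviance
  disc_stat <- d_null - d_full
  xp <- x_det[1, x_det[1, ] > 0]; gp <- g[x_det[1, ] > 0]
  rss1 <- sum(resid(lm(xp ~ gp))^2); rss0 <- sum(resid(lm(xp ~ 1))^2)
  cont_stat <- length(xp) * log(rss0 / rss1)
  expect_lt(cont_stat, 3)  # continuous part carries almost no signal
  expect_equal(res$p_value,
               stats::pchisq(disc_stat + cont_stat, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # all-zero gene gets a missing p-value
  expect_true(is.na(hurdle_test(mk_mat(rep(0, 80)), grp)$p_value))
  # one group with < 2 detected cells: discrete part only
  x_sparse <- mk_mat(c(rep(0, 39), 3, abs(rnorm(40, 2)) + 1))
  res_sp <- hurdle_test(x_sparse, grp)
  d_full <- stats::glm(as.integer(x_sparse[1, ] > 0) ~ g,
                       family = binomial())$deviance
  d_null <- stats::glm(as.integer(x_sparse[1, ] > 0) ~ 1,
                       family = binomial())$deviance
  expect_equal(res_sp$p_value,
               stats::pchisq(d_null - d_full, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("the mixed model collapses to OLS without subject variance", {
  set.seed(6)
  subj <- rep(paste0("s", 1:8), each = 25)
  grp <- factor(rep(c("A", "B"), each = 100))
  x <- mk_mat(rnorm(200) + 0.3 * (grp == "B"))  # zero subject variance
  res <- lmm_random_intercept_test(x, grp, subj)
  p_ols <- stats::t.test(x[1, grp == "A"], x[1, grp == "B"],
                         var.equal = TRUE)$p.value
  expect_lt(abs(res$p_value - p_ols), 0.02)
  # identical groups: high p
  x0 <- mk_mat(rep(rnorm(100), 2))
  expect_gt(lmm_random_intercept_test(x0, grp, subj)$p_value, 0.5)
  expect_error(lmm_random_intercept_test(x, grp, rep(c("s1", "s2"), each = 100)),
               "2 subjects")
})

test_that("moderated t equals the direct shrinkage formula and limma", {
  set.seed(8)
  x <- matrix(rnorm(50 * 8, sd = rep(sqrt(rchisq(50, 4) / 4), 8)), 50, 8)
  rownames(x) <- paste0("g", 1:50); colnames(x) <- paste0("s", 1:8)
  cond <- stats::setNames(rep(c("A", "B"), each = 4), colnames(x))
  pb <- dsbench:::.pseudobulk(x, "mean", "lognorm_mean", cond)
  res <- pb_moderated_t(pb)
  prm <- attr(res, "params")
  # independent direct evaluation of the shrinkage formula from raw moments
  m1 <- rowMeans(x[, 1:4]); m2 <- rowMeans(x[, 5:8])
  s2 <- (rowSums((x[, 1:4] - m1)^2) + rowSums((x[, 5:8] - m2)^2)) / 6
  s2_post <- (prm$d0 * prm$s0_2 + 6 * s2) / (prm$d0 + 6)
  t_direct <- (m2 - m1) / sqrt(s2_post * (1 / 4 + 1 / 4))
  p_direct <- 2 * stats::pt(-abs(t_direct), 6 + prm$d0)
  expect_equal(res$p_value, unname(p_direct), tolerance = 1e-9)
  # agreement with the established empirical-Bayes implementation
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, rep(0:1, each = 4))))
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 0.01)
  if (is.finite(prm$d0)) {
    expect_equal(prm$d0, fit$df.prior, tolerance = 0.1 * max(1, fit$df.prior))
  }
  # no-shrinkage limit: d0 = 0 reduces to the ordinary t-test
  p_ord <- 2 * stats::pt(-abs((m2 - m1) / sqrt(s2 / 2)), 6)
  t_d00 <- (m2 - m1) / sqrt(s2 * 0.5)
  expect_equal(p_ord, 2 * stats::pt(-abs(t_d00), 6))
})

test_that("pseudobulk NB Wald test nests Poisson and flags no false signal", {
  set.seed(10)
  x <- matrix(rnbinom(100 * 8, mu = 60, size = 4), 100, 8)
  rownames(x) <- paste0("g", 1:100); colnames(x) <- paste0("s", 1:8)
  cond <- stats::setNames(rep(c("A", "B"), each = 4), colnames(x))
  pb <- dsbench:::.pseudobulk(x, "sum", "raw", cond)
  # dispersion fixed at 0 reproduces the Poisson Wald p
  res0 <- pb_nbglm(pb, norm = "tmm", dispersion = 0)
  f <- tmm_factors(pb)
  off <- log(colSums(x) * f)
  g <- rep(0:1, each = 4)
  p_pois <- vapply(seq_len(100), function(i) {
    cf <- summary(stats::glm(x[i, ] ~ g, family = poisson(),
                             offset = off))$coefficients
    2 * stats::pnorm(-abs(cf["g", "Estimate"] / cf["g", "Std. Error"]))
  }, numeric(1))
  expect_equal(res0$p_value, p_pois, tolerance = 1e-6)
  # estimated-dispersion route: equal group means give flat p-values
  res <- pb_nbglm(pb, norm = "tmm")
  expect_gt(median(res$p_value, na.rm = TRUE), 0.2)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  # coefficient and Wald z against an independent NB likelihood maximization
  disp <- attr(res, "params")$dispersion[1]
  nll <- function(beta) {
    mu <- exp(beta[1] + beta[2] * g + off)
    -sum(stats::dnbinom(x[1, ], size = 1 / disp, mu = mu, log = TRUE))
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  expect_equal(res$effect[1] * log(2), opt$par[2], tolerance = 1e-4)
  # expected-information standard error computed from scratch
  mu_hat <- exp(opt$par[1] + opt$par[2] * g + off)
  w <- mu_hat / (1 + disp * mu_hat)
  X <- cbind(1, g)
  se_ind <- sqrt(solve(t(X) %*% (X * w))[2, 2])
  z_ind <- opt$par[2] / se_ind
  z_mine <- abs(stats::qnorm(res$p_value[1] / 2))
  expect_equal(z_mine, abs(z_ind), tolerance = 1e-4)
})

test_that("ROTS statistic reduces to known rankings and exact overlaps", {
  set.seed(12)
  x <- matrix(rnorm(20 * 8), 20, 8)
  rownames(x) <- paste0("g", 1:20); colnames(x) <- paste0("s", 1:8)
  ia <- 1:4; ib <- 5:8
  # (a1, a2) = (0, 1): ranking identical to the ordinary |t| ranking
  d01 <- dsbench:::.rots_stat(x, ia, ib, 0, 1)
  tstat <- vapply(1:20, function(i) {
    abs(stats::t.test(x[i, ia], x[i, ib], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(order(-d01), order(-tstat))
  # (a1, a2) = (1, 0): ranking by absolute mean difference
  d10 <- dsbench:::.rots_stat(x, ia, ib, 1, 0)
  md <- abs(rowMeans(x[, ia]) - rowMeans(x[, ib]))
  expect_equal(order(-d10), order(-md))
  # top-list overlap equals brute-force set intersection
  for (k in c(3, 5, 10)) {
    d2 <- rnorm(20)
    top1 <- order(-d01, seq_along(d01))[1:k]
    top2 <- order(-d2, seq_along(d2))[1:k]
    expect_equal(dsbench:::.top_overlap(d01, d2, k),
                 length(intersect(top1, top2)) / k)
  }
  # end-to-end on a tiny instance: valid p-values, deterministic under seed
  cond <- stats::setNames(rep(c("A", "B"), each = 4), colnames(x))
  pb <- dsbench:::.pseudobulk(x, "mean", "lognorm_mean", cond)
  r1 <- pb_rots(pb, n_bootstrap = 10, n_perm_p = 20, seed = 3)
  r2 <- pb_rots(pb, n_bootstrap = 10, n_perm_p = 20, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
})

test_that("all tests are two-sided: invariant to swapping condition labels", {
  sim <- tiny_sim(g = 30, s = 6, cps = 25, n_de = 5, seed = 21)
  d <- sim$data
  flipped <- cell_counts(d$counts, as.character(d$cell_sample),
                         stats::setNames(ifelse(d$sample_condition == "A",
                                                "B", "A"),
                                         names(d$sample_condition)),
                         gene_ids = d$gene_ids)
  for (m in c("wilcoxon", "poisson", "pb_modt_sum")) {
    p1 <- run_ds_method(d, m)$p_value
    p2 <- run_ds_method(flipped, m)$p_value
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("naive tests hold their nominal size on their own null models", {
  # iid data with no subject effect; each test gets data matching its noise
  # model (near-Poisson counts for the Poisson GLM)
  sim_w <- tiny_sim(g = 2000, s = 6, cps = 70, n_de = 0, theta = 1e6,
                    phi = 0.2, seed = 31)
  pw <- run_ds_method(sim_w$data, "wilcoxon")$p_value
  rate_w <- mean(pw < 0.05, na.rm = TRUE)
  expect_gt(rate_w, 0.03); expect_lt(rate_w, 0.07)

  sim_p <- tiny_sim(g = 2000, s = 6, cps = 70, n_de = 0, theta = 1e6,
                    phi = 1e-3, seed = 32)
  pp <- run_ds_method(sim_p$data, "poisson")$p_value
  rate_p <- mean(pp < 0.05, na.rm = TRUE)
  expect_gt(rate_p, 0.03); expect_lt(rate_p, 0.07)

  sim_l <- tiny_sim(g = 1000, s = 6, cps = 50, n_de = 0, theta = 1e6,
                    phi = 0.2, seed = 33)
  pl <- run_ds_method(sim_l$data, "lr")$p_value
  rate_l <- mean(pl < 0.05, na.rm = TRUE)
  expect_gt(rate_l, 0.025); expect_lt(rate_l, 0.075)
})

test_that("pseudoreplication inflates naive rejections but not pseudobulk", {
  # hierarchical null: strong subject effects, no true signal
  sim <- tiny_sim(g = 2000, s = 10, cps = 60, n_de = 0, theta = 0.1,
                  phi = 0.2, seed = 41)
  p_naive <- run_ds_method(sim$data, "wilcoxon")$p_value
  expect_gt(mean(p_naive < 0.05, na.rm = TRUE), 0.10)
  p_pb <- run_ds_method(sim$data, "pb_modt_sum")$p_value
  rate_pb <- mean(p_pb < 0.05, na.rm = TRUE)
  expect_gt(rate_pb, 0.02); expect_lt(rate_pb, 0.08)
})

test_that("latent subject covariates keep the group test df at one", {
  sim <- tiny_sim(g = 20, s = 6, cps = 25, n_de = 5, seed = 51)
  res <- run_ds_method(sim$data, "poisson_latent")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  res2 <- run_ds_method(sim$data, "lr_latent")
  expect_true(all(res2$p_value >= 0 & res2$p_value <= 1, na.rm = TRUE))
})
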