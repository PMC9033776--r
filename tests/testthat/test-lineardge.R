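test_that("cell-means design matches the study layout and contrast identities", {
  des <- build_design(study_samples())
  expect_equal(dim(des$design), c(14L, 4L))
  expect_equal(unname(colSums(des$design)), c(4, 3, 4, 3))
  expect_true(all(rowSums(des$design) == 1))

  syn <- des$contrasts[, "SYNERGY"]
  expect_equal(sum(syn), 0)
  expect_equal(unname(syn["SZ_JQ"] + syn["CTRL_VEH"]), 2)
  expect_equal(unname(syn["SZ_VEH"] + syn["CTRL_JQ"]), -2)
  expect_equal(sort(unique(abs(syn))), 1)

  expect_error(build_design(data.frame(diagnosis = "BAD", treatment = "VEH")),
               "diagnosis")
})

test_that("permuting sample rows permutes the design but not the fit", {
  sim <- null_sim(n_genes = 60, seed = 2)
  counts <- filter_low_expression(sim$counts)
  expr <- log_cpm(counts, tmm_factors(counts))
  des <- build_design(sim$samples)
  fit <- fit_contrasts(expr, NULL, des$design, des$contrasts)

  perm <- sample(ncol(expr))
  des_p <- build_design(sim$samples[perm, ])
  fit_p <- fit_contrasts(expr[, perm], NULL, des_p$design, des_p$contrasts)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-12)
  expect_equal(fit$sigma, fit_p$sigma, tolerance = 1e-12)
})

test_that("mean-variance weights are flat under homoscedastic noise and clamped", {
  set.seed(10)
  des <- build_design(study_samples())
  expr <- matrix(rnorm(500 * 14, mean = rep(runif(500, 2, 10), 14), sd = 0.5),
                 500, 14, dimnames = list(paste0("g", 1:500), NULL))
  vw <- mean_variance_weights(expr, des$design)
  expect_true(all(vw$weights > 0))
  band <- vw$weights / median(vw$weights)
  expect_gt(mean(band > 0.5 & band < 2), 0.99)

  # outside the fitted range the boundary trend value applies
  lo <- vw$trend
  w_out <- stats::approx(lo$x, lo$y, xout = c(min(lo$x) - 10, max(lo$x) + 10),
                         rule = 2)$y
  expect_equal(w_out, c(lo$y[1], lo$y[length(lo$y)]))
})

test_that("weights decrease toward low counts under NB overdispersion", {
  sim <- null_sim(n_genes = 2000, seed = 6)
  counts <- filter_low_expression(sim$counts)
  f <- tmm_factors(counts)
  expr <- log_cpm(counts, f)
  des <- build_design(sim$samples)
  vw <- mean_variance_weights(expr, des$design,
                              lib_size = attr(f, "effective_lib_size"))
  a <- rowMeans(expr)
  dec <- cut(a, breaks = quantile(a, 0:10 / 10), include.lowest = TRUE)
  wmean <- tapply(rowMeans(vw$weights), dec, mean)
  expect_lt(wmean[1], wmean[10])
})

test_that("weighted least squares matches closed forms and a generic oracle", {
  # two-group toy: coefficient = group mean difference, pooled variance
  y <- matrix(c(1, 2, 3, 7, 8, 9), 1)
  X <- cbind(a = rep(c(1, 0), each = 3), b = rep(c(0, 1), each = 3))
  co <- matrix(c(-1, 1), 2, dimnames = list(c("a", "b"), "b_vs_a"))
  fit <- fit_contrasts(y, NULL, X, co)
  expect_equal(unname(fit$coefficients[1, 1]), 6)
  expect_equal(fit$sigma[1]^2, 1)          # pooled var of (1,2,3)/(7,8,9)
  expect_equal(unname(fit$stdev_unscaled[1, 1]), sqrt(1 / 3 + 1 / 3))

  # 50 random genes against lm() as an independent WLS routine
  set.seed(42)
  sim <- null_sim(n_genes = 80, seed = 13)
  counts <- filter_low_expression(sim$counts)
  expr <- log_cpm(counts, tmm_factors(counts))[1:50, , drop = FALSE]
  w <- matrix(runif(length(expr), 0.2, 5), nrow(expr))
  des <- build_design(sim$samples)
  fit2 <- fit_contrasts(expr, w, des$design, des$contrasts)
  for (g in c(1, 17, 50)) {
    lmfit <- lm(expr[g, ] ~ 0 + des$design, weights = w[g, ])
    beta <- coef(lmfit)
    V <- summary(lmfit)$cov.unscaled
    for (k in colnames(des$contrasts)) {
      cv <- des$contrasts[, k]
      expect_equal(unname(fit2$coefficients[g, k]), unname(sum(cv * beta)),
                   tolerance = 1e-10)
      expect_equal(unname(fit2$stdev_unscaled[g, k]),
                   unname(sqrt(drop(t(cv) %*% V %*% cv))), tolerance = 1e-10)
    }
    expect_equal(fit2$sigma[g], summary(lmfit)$sigma, tolerance = 1e-10)
  }

  # interaction linearity: SYNERGY = SZJQ - SZ - JQ
  expect_lt(max(abs(fit2$coefficients[, "SYNERGY"] -
                      (fit2$coefficients[, "SZJQ_vs_CTRL"] -
                         fit2$coefficients[, "SZ_vs_CTRL"] -
                         fit2$coefficients[, "JQ_vs_CTRL"]))), 1e-10)

  expect_error(fit_contrasts(expr, w, des$design[, c(1, 1, 2, 3)],
                             des$contrasts), "full rank")
})

test_that("moderation reproduces its limiting cases and recovers the prior", {
  sim <- null_sim(n_genes = 300, seed = 21)
  counts <- filter_low_expression(sim$counts)
  expr <- log_cpm(counts, tmm_factors(counts))
  des <- build_design(sim$samples)
  fit <- fit_contrasts(expr, NULL, des$design, des$contrasts)

  # forced d0 = 0: ordinary t statistics
  m0 <- moderate_statistics(fit, prior_df = 0)
  t_ord <- fit$coefficients / (fit$stdev_unscaled * fit$sigma)
  expect_equal(m0$t, t_ord, tolerance = 1e-12)

  # equal variances: the estimator drives d0 to infinity and t uses s0
  fit_eq <- fit
  fit_eq$sigma <- rep(0.7, length(fit$sigma))
  meq <- moderate_statistics(fit_eq)
  expect_true(is.infinite(meq$d0))
  expect_equal(meq$t, fit_eq$coefficients / (fit_eq$stdev_unscaled *
                                               sqrt(meq$s0_2)),
               tolerance = 1e-10)
  expect_true(all(meq$s2_post == meq$s0_2))
  # the log-variance bias correction puts s0^2 near the common variance
  expect_lt(abs(meq$s0_2 / 0.49 - 1), 0.15)

  # posterior variance is a convex combination of s0^2 and s^2
  m1 <- moderate_statistics(fit)
  lo <- pmin(m1$s0_2, fit$sigma^2); hi <- pmax(m1$s0_2, fit$sigma^2)
  expect_true(all(m1$s2_post >= lo - 1e-12 & m1$s2_post <= hi + 1e-12))

  # scaling all weights leaves moderated t and p unchanged
  w <- matrix(1, nrow(expr), ncol(expr))
  fa <- moderate_statistics(fit_contrasts(expr, w, des$design, des$contrasts))
  fb <- moderate_statistics(fit_contrasts(expr, 5 * w, des$design,
                                          des$contrasts))
  expect_equal(fa$t, fb$t, tolerance = 1e-10)
  expect_equal(fa$p, fb$p, tolerance = 1e-10)
})

test_that("prior parameters are recovered from scaled-F distributed variances", {
  set.seed(99)
  G <- 5000; d <- 10L; d0_true <- 10; s0_true <- 0.5
  sigma2 <- d0_true * s0_true / rchisq(G, d0_true)   # inverse-chisq prior
  s2 <- sigma2 * rchisq(G, d) / d
  fake <- structure(list(
    coefficients = matrix(0, G, 1), stdev_unscaled = matrix(1, G, 1),
    sigma = sqrt(s2), df_residual = rep(d, G)), class = "contrast_fit")
  m <- moderate_statistics(fake)
  expect_gte(m$d0, 6); expect_lte(m$d0, 16)
  expect_lt(abs(m$s0_2 / s0_true - 1), 0.2)
})

test_that("moderated statistics agree with the established EB implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_counts(sim_config(n_genes = 800, seed = 31))
  fit <- dge_fit(sim$counts, sim$samples)
  v <- limma::voom(fit$counts, fit$design,
                   lib.size = attr(fit$norm_factors, "effective_lib_size"))
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(v, fit$design),
                                           fit$contrasts))
  expect_equal(unname(fit$weights), unname(v$weights), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(eb$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(fit$t), unname(eb$t), tolerance = 1e-8)
  expect_equal(fit$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, eb$s2.prior, tolerance = 1e-6)
})

test_that("BH adjustment matches the hand computation and controls the null", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # hand step-up on an unsorted vector
  p <- c(0.9, 0.001, 0.02, 0.03, 0.5)
  n <- length(p); o <- order(p)
  q_hand <- numeric(n)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_hand[o] <- pmin(q_sorted, 1)
  expect_equal(adjust_fdr(p), q_hand)

  set.seed(7)
  fr <- replicate(20, mean(adjust_fdr(runif(2000)) <= 0.05))
  expect_lte(mean(fr), 0.05)
})
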