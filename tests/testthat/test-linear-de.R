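norm_sim <- function(n_probes = 600, seed = 1, rho = 0.2, ...) {
  simulate_experiment(simulation_config(
    n_probes = n_probes, sigma_block = sigma_block_for_rho(rho),
    output_scale = "normalized", seed = seed, ...))
}

test_that("two-group GLS at zero correlation reproduces the closed-form group means", {
  ee <- toy_experiment(c(1, 2, 3, 4), groups = c("A", "A", "B", "B"),
                       blocks = c("b1", "b2", "b1", "b2"))
  des <- design_spec(ee$samples$group, ee$samples$block, list(BA = "B-A"))
  fit <- fit_gls(ee, des, rho = 0)
  expect_equal(unname(fit$coefficients[1, ]), c(1.5, 3.5))
  expect_equal(unname(fit$sigma2), 0.5)
  expect_equal(fit$df_residual, 2)
  tab <- contrast_tests(fit, list(d0 = 0, s0sq = 1), "BA")
  expect_equal(tab$logFC, 2.0)
  # ordinary t: 2 / sqrt(0.5 * (1/2 + 1/2)) = 2 / sqrt(0.5)
  expect_equal(tab$t, 2 / sqrt(0.5))
  expect_equal(tab$p_value, 2 * pt(-2 / sqrt(0.5), df = 2))
})

test_that("GLS at rho = 0 equals ordinary least squares probe by probe", {
  sim <- norm_sim(80, seed = 41)
  ee <- sim$experiment
  des <- design_spec(ee$samples$group, ee$samples$block,
                     sim$truth$config$contrasts)
  fit <- fit_gls(ee, des, rho = 0)
  X <- model.matrix(~ 0 + factor(ee$samples$group))
  for (g in c(1, 40, 80)) {
    ols <- lm.fit(X, ee$intensities[g, ])
    expect_lt(max(abs(fit$coefficients[g, ] - ols$coefficients)), 1e-10)
    expect_lt(abs(fit$sigma2[g] - sum(ols$residuals^2) / ols$df.residual), 1e-10)
  }
})

test_that("fitting is invariant to jointly permuting samples and annotations", {
  sim <- norm_sim(60, seed = 42)
  ee <- sim$experiment
  perm <- sample(ncol(ee$intensities))
  des <- design_spec(ee$samples$group, ee$samples$block,
                     sim$truth$config$contrasts)
  fit <- fit_gls(ee, des, rho = 0.2)
  eep <- ee[, perm]
  desp <- design_spec(eep$samples$group, eep$samples$block,
                      sim$truth$config$contrasts)
  fitp <- fit_gls(eep, desp, rho = 0.2)
  expect_equal(fit$coefficients, fitp$coefficients, tolerance = 1e-10)
  expect_equal(fit$sigma2, fitp$sigma2, tolerance = 1e-10)
})

test_that("a design with an empty group names the aliased level", {
  ee <- toy_experiment(rnorm(8), groups = rep(c("A", "B"), each = 4),
                       blocks = rep(c("b1", "b2"), 4))
  # constructed directly: the constructor itself drops unused levels
  des <- structure(list(group = factor(ee$samples$group,
                                       levels = c("A", "B", "C")),
                        block = factor(ee$samples$block),
                        contrasts = list()),
                   class = "design_spec")
  expect_error(fit_gls(ee, des, rho = 0), "aliased.*C")
  des_ok <- design_spec(ee$samples$group, ee$samples$block, list())
  expect_error(fit_gls(ee, des_ok, rho = 1.5), "admissible")
})

test_that("consensus correlation recovers planted block correlations", {
  sim0 <- norm_sim(2000, seed = 51, rho = 0)
  des0 <- design_spec(sim0$experiment$samples$group,
                      sim0$experiment$samples$block,
                      sim0$truth$config$contrasts)
  rho0 <- estimate_consensus_correlation(sim0$experiment, des0)
  expect_lt(abs(as.numeric(rho0)), 0.05)

  sim3 <- norm_sim(2000, seed = 52, rho = 0.3)
  des3 <- design_spec(sim3$experiment$samples$group,
                      sim3$experiment$samples$block,
                      sim3$truth$config$contrasts)
  rho3 <- estimate_consensus_correlation(sim3$experiment, des3)
  expect_gte(as.numeric(rho3), 0.2)
  expect_lte(as.numeric(rho3), 0.4)
})

test_that("consensus correlation matches the established random-effect estimator", {
  skip_if_not_installed("limma")
  sim <- norm_sim(500, seed = 53, rho = 0.25)
  ee <- sim$experiment
  des <- design_spec(ee$samples$group, ee$samples$block,
                     sim$truth$config$contrasts)
  ours <- as.numeric(estimate_consensus_correlation(ee, des))
  X <- model.matrix(~ 0 + factor(ee$samples$group))
  theirs <- limma::duplicateCorrelation(ee$intensities, X,
                                        block = ee$samples$block)$consensus.correlation
  expect_lt(abs(ours - theirs), 0.02)
})

test_that("duplicated samples within blocks drive the correlation to the upper clamp", {
  set.seed(54)
  G <- 150
  base <- matrix(rnorm(G * 4), G, 4)       # one value per block
  y <- base[, rep(1:4, each = 2)] + matrix(rnorm(G * 8, 0, 1e-4), G, 8)
  ee <- toy_experiment(y, groups = rep("A", 8),
                       blocks = rep(paste0("b", 1:4), each = 2))
  des <- design_spec(ee$samples$group, ee$samples$block, list())
  rho <- estimate_consensus_correlation(ee, des)
  expect_gt(as.numeric(rho), 0.98)
})

test_that("a single block is rejected with advice to use ordinary least squares", {
  ee <- toy_experiment(rnorm(20), groups = rep(c("A", "B"), 5),
                       blocks = rep("b1", 10))
  des <- design_spec(ee$samples$group, ee$samples$block, list())
  expect_error(estimate_consensus_correlation(ee, des), "ordinary least squares")
})

test_that("the variance-prior estimator handles degenerate and scaled inputs", {
  fit_const <- list(sigma2 = rep(0.04, 100), df_residual = 10)
  mp <- moderate(fit_const)
  expect_true(is.infinite(mp$d0))
  expect_equal(mp$s0sq, 0.04)

  set.seed(55)
  s2 <- 0.05 * 4 / rchisq(3000, 4) * rchisq(3000, 16) / 16
  mp1 <- moderate(list(sigma2 = s2, df_residual = 16))
  mp2 <- moderate(list(sigma2 = 2 * s2, df_residual = 16))
  expect_equal(mp2$d0, mp1$d0, tolerance = 1e-8)
  expect_equal(mp2$s0sq, 2 * mp1$s0sq, tolerance = 1e-8)

  expect_error(moderate(list(sigma2 = rep(1, 5), df_residual = 4)),
               "fewer than 10")
})

test_that("prior parameters are recovered from their own sampling model", {
  set.seed(56)
  sigma2 <- 0.05 * 4 / rchisq(5000, 4)
  s2 <- sigma2 * rchisq(5000, 18) / 18
  mp <- moderate(list(sigma2 = s2, df_residual = 18))
  expect_gt(mp$d0, 3.2); expect_lt(mp$d0, 4.8)
  expect_gt(mp$s0sq, 0.04); expect_lt(mp$s0sq, 0.06)
})

test_that("the prior estimator agrees with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(57)
  s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 18) / 18
  mp <- moderate(list(sigma2 = s2, df_residual = 18))
  ff <- limma::fitFDist(s2, df1 = 18)
  expect_equal(mp$d0, ff$df2, tolerance = 1e-6)
  expect_equal(mp$s0sq, ff$scale, tolerance = 1e-6)
})

test_that("moderated tests shrink variances and reduce to known limits", {
  sim <- norm_sim(400, seed = 58)
  ee <- sim$experiment
  des <- design_spec(ee$samples$group, ee$samples$block,
                     sim$truth$config$contrasts)
  fit <- fit_gls(ee, des, rho = 0)
  mp <- moderate(fit)

  # d0 = 0 reproduces the ordinary t-statistic
  tab0 <- contrast_tests(fit, list(d0 = 0, s0sq = 1), "OSE4_OSE0")
  cvec <- as_contrast_vector("OSE4-OSE0", colnames(fit$coefficients))
  u <- sqrt(drop(t(cvec) %*% fit$cov_unscaled %*% cvec))
  t_manual <- (fit$coefficients %*% cvec) / (u * sqrt(fit$sigma2))
  expect_equal(tab0$t, as.vector(t_manual))

  # d0 = Inf with equal group sizes equals a z-test with the prior variance
  tabInf <- contrast_tests(fit, list(d0 = Inf, s0sq = mp$s0sq), "OSE4_OSE0")
  z <- as.vector(fit$coefficients %*% cvec) / (u * sqrt(mp$s0sq))
  expect_equal(tabInf$t, z)
  expect_equal(tabInf$p_value, 2 * pnorm(-abs(z)))

  # |t| increases with |logFC| at fixed variance
  tab <- contrast_tests(fit, mp, "OSE4_OSE0")
  expect_error(contrast_tests(fit, mp, "NOPE-ALSO_NOPE"), "contrast")
  ord <- order(abs(tab$logFC / sqrt((mp$d0 * mp$s0sq + fit$df_residual * fit$sigma2))))
  expect_true(all(diff(abs(tab$t)[ord]) > -1e-12))

  # adjusted p-values dominate raw ones; direction matches the sign
  expect_true(all(tab$adj_p_value >= tab$p_value - 1e-15))
  expect_gte(min(tab$adj_p_value), min(tab$p_value))
  expect_true(all(tab$direction[tab$significant] ==
                    ifelse(tab$logFC[tab$significant] > 0, "up", "down")))
})

test_that("moderated tests agree with the established blocked pipeline", {
  skip_if_not_installed("limma")
  sim <- norm_sim(500, seed = 59, rho = 0.25)
  ee <- sim$experiment
  des <- design_spec(ee$samples$group, ee$samples$block,
                     sim$truth$config$contrasts)
  rho <- as.numeric(estimate_consensus_correlation(ee, des))
  fit <- fit_gls(ee, des, rho = rho)
  tab <- contrast_tests(fit, moderate(fit), "OSE4_OSE0")

  X <- model.matrix(~ 0 + factor(ee$samples$group))
  colnames(X) <- levels(factor(ee$samples$group))
  lf <- limma::lmFit(ee$intensities, X, block = ee$samples$block,
                     correlation = rho)
  cm <- limma::makeContrasts(OSE4 - OSE0, levels = X)
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_equal(tab$logFC, unname(eb$coefficients[, 1]), tolerance = 1e-8)
  expect_equal(tab$t, unname(eb$t[, 1]), tolerance = 1e-4)
  expect_equal(tab$p_value, unname(eb$p.value[, 1]), tolerance = 1e-4)
})

test_that("raw p-values are calibrated under the null", {
  fracs <- vapply(1:10, function(s) {
    sim <- norm_sim(400, seed = 600 + s, de_prop = 0)
    ee <- sim$experiment
    des <- design_spec(ee$samples$group, ee$samples$block,
                       sim$truth$config$contrasts)
    fit <- fit_gls(ee, des, rho = 0.2)
    tab <- contrast_tests(fit, moderate(fit), "OSE4_OSE0")
    mean(tab$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 4000))
})
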