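make_detection_toy <- function() {
  det <- rbind(rep(1.0, 4),
               rep(0.01, 4),
               c(0.01, 0.01, 0.01, 0.2),
               rep(0.2, 4),
               rep(0.01, 4))
  vals <- matrix(100, 5, 4)
  expression_experiment(
    vals, det,
    samples = data.frame(sample_id = paste0("s", 1:4), group = "A",
                         block = c("b1", "b1", "b2", "b2")),
    probes = data.frame(probe_id = paste0("p", 1:5),
                        gene_id = paste0("g", 1:5),
                        quality = c("good", "good", "good", "good", "no_match")),
    scale = "raw")
}

test_that("the detection/quality filter retains reliably detected, well-annotated probes", {
  ee <- make_detection_toy()
  out <- filter_probes(ee, detect_alpha = 0.05, detected_fraction = 0.75)
  expect_equal(out$probes$probe_id, c("p2", "p3"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_input, 5)
  expect_equal(rep$n_retained, 2)

  # quality trumps detection; detection trumps quality
  expect_false("p5" %in% out$probes$probe_id)     # detected but no_match
  expect_false("p1" %in% out$probes$probe_id)     # good but undetected
  expect_error(filter_probes(ee, detected_fraction = 1.5), "detected_fraction")
})

test_that("probe filtering is idempotent and never increases the probe count", {
  sim <- simulate_experiment(simulation_config(n_probes = 500, seed = 8))
  f1 <- filter_probes(sim$experiment)
  f2 <- filter_probes(f1)
  expect_lte(nrow(f1$intensities), nrow(sim$experiment$intensities))
  expect_equal(f1$probes$probe_id, f2$probes$probe_id)
})

test_that("the literal removal rule discards well-detected probes", {
  ee <- make_detection_toy()
  lit <- filter_probes(ee, detected_fraction = 0.9, literal = TRUE)
  # 'removed if detection p < 0.05 in > 10% of samples' kills probes 2, 3, 5
  expect_equal(lit$probes$probe_id, c("p1", "p4"))
})

test_that("the glog transform preserves per-sample rank order", {
  sim <- simulate_experiment(simulation_config(n_probes = 800, seed = 14))
  pre <- filter_probes(sim$experiment, drop_quality = character(0))
  nrm <- vst_transform(pre)
  for (j in seq_len(ncol(pre$intensities)))
    expect_equal(order(pre$intensities[, j]), order(nrm$intensities[, j]))
  expect_equal(nrm$scale, "normalized")
  expect_error(vst_transform(nrm), "raw-scale")
})

test_that("with no additive component the transform reduces to the logarithm", {
  set.seed(15)
  baseline <- rnorm(400, 8, 1)
  y <- 2^(baseline + matrix(rnorm(400 * 6, 0, 0.2), 400))
  ee <- expression_experiment(
    y, NULL,
    samples = data.frame(sample_id = paste0("s", 1:6), group = "A",
                         block = rep(c("b1", "b2"), 3)),
    probes = data.frame(probe_id = paste0("p", 1:400),
                        gene_id = paste0("g", 1:400), quality = "good"),
    scale = "raw")
  nrm <- vst_transform(ee, c = 1e-12, background = list(mean = 0, sd = 0))
  for (j in 1:6)
    expect_gt(cor(nrm$intensities[, j], log2(y[, j])), 0.999)
})

test_that("the transform flattens the raw-scale mean-variance relationship", {
  sim <- simulate_experiment(simulation_config(n_probes = 2000, seed = 16))
  pre <- filter_probes(sim$experiment, drop_quality = character(0))
  grp <- pre$samples$group
  rep_sd <- function(m) rowMeans(sapply(split(seq_along(grp), grp), function(ix)
    apply(m[, ix, drop = FALSE], 1, sd)))
  mu <- rowMeans(pre$intensities)
  dec <- cut(mu, quantile(mu, c(0, 0.1, 0.9, 1)), include.lowest = TRUE,
             labels = c("bottom", "mid", "top"))
  ratio <- function(s) median(s[dec == "top"]) / median(s[dec == "bottom"])
  expect_gte(ratio(rep_sd(pre$intensities)), 5)
  nrm <- vst_transform(pre)
  expect_lte(ratio(rep_sd(nrm$intensities)), 2)
})

test_that("the robust calibration line agrees with least-trimmed-squares reference fits", {
  skip_if_not_installed("MASS")
  set.seed(18)
  x <- rnorm(500, 100, 30)
  y <- 5 + 2 * x + rnorm(500, 0, 2)
  out <- sample(500, 50)
  y[out] <- y[out] + 200  # outliers the trimmed fit must resist
  ours <- eaetx:::lts_line(x, y, trim = 0.2)
  ref <- MASS::lqs(y ~ x, method = "lts", quantile = floor(500 * 0.8))
  expect_equal(unname(ours["b"]), unname(coef(ref)[2]), tolerance = 0.02)
  expect_lt(abs(ours["b"] - 2), 0.05)
})

test_that("normalization commutes with sample reordering", {
  sim <- simulate_experiment(simulation_config(n_probes = 300, seed = 19))
  pre <- filter_probes(sim$experiment, drop_quality = character(0))
  perm <- sample(ncol(pre$intensities))
  a <- vst_transform(pre)
  b <- vst_transform(pre[, perm])
  expect_equal(b$intensities, a$intensities[, perm])
})

test_that("principal components pick up a planted block effect but not a null one", {
  cfg <- simulation_config(n_probes = 700, sigma_block = 5,
                           de_prop = 0, output_scale = "normalized", seed = 22)
  sim <- simulate_experiment(cfg)
  ba <- batch_association(sim$experiment, n_pcs = 5)
  expect_lt(ba$p_value[ba$pc == 1 & ba$factor == "block"], 1e-4)

  hits <- 0; total <- 0
  for (s in 1:20) {
    cfg0 <- simulation_config(n_probes = 150, sigma_block = 0, de_prop = 0,
                              output_scale = "normalized", seed = 100 + s)
    ba0 <- batch_association(simulate_experiment(cfg0)$experiment, n_pcs = 5)
    p <- ba0$p_value[ba0$factor == "block"]
    hits <- hits + sum(p < 0.05); total <- total + length(p)
  }
  expect_lt(abs(hits / total - 0.05), 2.58 * sqrt(0.05 * 0.95 / total))
})

test_that("degenerate technical factors and excess components are handled gracefully", {
  sim <- simulate_experiment(simulation_config(n_probes = 120, seed = 23,
                                               output_scale = "normalized"))
  one_block <- sim$experiment
  one_block$samples$block <- "b1"
  one_block$samples$position <- seq_len(nrow(one_block$samples))
  w <- capture_warnings(batch_association(one_block, n_pcs = 3))
  expect_true(all(grepl("degenerate", w)))
  expect_length(w, 2)  # both block and per-sample position are degenerate here
  expect_warning(batch_association(sim$experiment, n_pcs = 40), "truncated")
})
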