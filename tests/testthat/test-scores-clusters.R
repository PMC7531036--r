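test_that("gene-set PC scores expose the dominant axis with a deterministic sign", {
  # rank-1 submatrix: one component carries all the variance
  set.seed(31)
  v <- rnorm(12)
  load <- runif(6, 0.5, 1.5)
  y <- outer(load, v)   # probes x samples, rank 1
  ee <- toy_experiment(y, groups = rep(c("A", "B"), 6),
                       blocks = rep(c("b1", "b2"), each = 6),
                       gene_id = paste0("gene", 1:6))
  sc <- geneset_pc_scores(ee, paste0("gene", 1:6), n_components = 2)
  expect_equal(sc$var_explained[1], 1, tolerance = 1e-10)
  expect_gt(sum(sc$loadings[, 1]), 0)
  expect_equal(unname(apply(sc$scores, 2, sd)), rep(1, 2))

  expect_error(geneset_pc_scores(ee, c("nope1", "nope2")), "nope1")
})

test_that("scores are invariant to sample order, probe shifts, and probe duplication", {
  sim <- simulate_experiment(simulation_config(n_probes = 200, seed = 32,
                                               output_scale = "normalized"))
  ee <- sim$experiment
  genes <- unique(ee$probes$gene_id)[1:30]
  sc <- geneset_pc_scores(ee, genes)

  perm <- sample(ncol(ee$intensities))
  sc_perm <- geneset_pc_scores(ee[, perm], genes)
  expect_equal(sc_perm$scores[, 1],
               sc$scores[perm, 1], tolerance = 1e-8,
               ignore_attr = TRUE)

  shifted <- ee
  shifted$intensities <- ee$intensities + rnorm(nrow(ee$intensities))
  expect_equal(geneset_pc_scores(shifted, genes)$scores[, 1], sc$scores[, 1],
               tolerance = 1e-8)

  # duplicating every selected probe leaves standardized PC1 unchanged
  idx <- which(ee$probes$gene_id %in% genes)
  dup <- expression_experiment(
    rbind(ee$intensities, ee$intensities[idx, , drop = FALSE]), NULL,
    samples = ee$samples,
    probes = rbind(ee$probes,
                   transform(ee$probes[idx, ],
                             probe_id = paste0(probe_id, "_dup"))),
    scale = "normalized")
  sc_dup <- geneset_pc_scores(dup, genes)
  expect_equal(abs(sc_dup$scores[, 1]), abs(sc$scores[, 1]), tolerance = 1e-8)
})

test_that("a planted group shift orders the first-component means accordingly", {
  ok <- 0
  for (s in 1:10) {
    cfg <- simulation_config(groups = c("CTL", "DIS"), n_blocks = 2,
                             n_probes = 300, contrasts = list(D = "DIS-CTL"),
                             de_prop = c(D = 0.5), effect_size = 2,
                             output_scale = "normalized", seed = 700 + s)
    sim <- simulate_experiment(cfg)
    genes <- unique(sim$truth$gene_map$gene_id[
      sim$truth$de[, "D"][match(unique(sim$truth$gene_map$gene_id),
                                sim$truth$gene_map$gene_id)]])
    genes <- intersect(sim$truth$de_genes$D, sim$truth$gene_map$gene_id)
    sc <- geneset_pc_scores(sim$experiment, genes)
    m <- tapply(sc$scores[, 1], sim$experiment$samples$group, mean)
    if (abs(m["DIS"] - m["CTL"]) > 1) ok <- ok + 1
  }
  expect_equal(ok, 10)
})

test_that("group comparisons reproduce the Welch closed form and boundary cases", {
  res <- compare_score_groups(c(1, 2, 3, 3, 4, 5),
                              groups = c("A", "A", "A", "B", "B", "B"),
                              control_groups = "A")
  expect_equal(res$statistic, 2.449, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0705, tolerance = 1e-2)

  # identical distributions: p = 1
  res2 <- compare_score_groups(c(1, 2, 3, 1, 2, 3),
                               groups = rep(c("A", "B"), each = 3),
                               control_groups = "A")
  expect_equal(res2$p_value, 1)

  expect_warning(
    compare_score_groups(c(1, 2, 3, 4), groups = c("A", "A", "A", "B"),
                         control_groups = "A"),
    "fewer than 2")

  # planted separation far beyond noise: *** stars
  set.seed(33)
  sc <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  res3 <- compare_score_groups(sc, rep(c("CTL", "DIS"), each = 8), "CTL")
  expect_lt(res3$adj_p_value, 0.001)
  expect_equal(res3$stars, "***")

  res4 <- compare_score_groups(sc, rep(c("CTL", "DIS"), each = 8), "CTL",
                               test = "wilcoxon")
  expect_lt(res4$p_value, 0.01)
})

test_that("k-means stability finds a fully stable solution on separated blobs", {
  set.seed(34)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
               matrix(rnorm(20, 5, 0.1), ncol = 2))
  ks <- kmeans_stability(pts, k = 2, n_rep = 100, seed = 35)
  expect_equal(ks$modal_freq, 100)
  expect_equal(sum(ks$records$freq), 100)
  expect_error(kmeans_stability(pts, k = 25), "exceeds")

  ks2 <- kmeans_stability(pts, k = 2, n_rep = 50, seed = 35)
  expect_equal(ks2$modal, ks$modal)
})

test_that("canonicalization is label-invariant", {
  lab <- c(2, 2, 1, 3, 1, 3)
  relabeled <- c(1, 1, 3, 2, 3, 2)
  expect_equal(eaetx:::canonical_partition(lab),
               eaetx:::canonical_partition(relabeled))
  expect_equal(eaetx:::canonical_partition(lab)[1], 1)
})

test_that("the modal partition attains the brute-force optimal within-cluster sum of squares", {
  set.seed(36)
  pts <- matrix(c(rnorm(8, 0, 0.4), rnorm(8, 4, 0.4)), ncol = 2)
  # exhaustive search over all 2-partitions of 8 points
  best <- Inf; best_part <- NULL
  for (code in 1:(2^7 - 1)) {
    lab <- c(1, as.integer(intToBits(code))[1:7] + 1)
    if (length(unique(lab)) < 2) next
    wss <- sum(sapply(split(seq_len(8), lab), function(ix)
      sum(scale(pts[ix, , drop = FALSE], scale = FALSE)^2)))
    if (wss < best) { best <- wss; best_part <- eaetx:::canonical_partition(lab) }
  }
  ks <- kmeans_stability(pts, k = 2, n_rep = 50, seed = 37)
  expect_equal(ks$modal, best_part)
  expect_equal(ks$records$tot_withinss[1], best, tolerance = 1e-8)
})

test_that("bipartition respect counts repeats with fully separated sides", {
  parts <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 1, 1, 1))
  expect_equal(bipartition_respect(parts, 1:2, 3:4), 1 / 3)
  expect_equal(bipartition_respect(list(rep(1, 4)), 1:2, 3:4), 0)
  set.seed(38)
  pts <- rbind(matrix(rnorm(24, 0, 0.2), ncol = 2),
               matrix(rnorm(24, 6, 0.2), ncol = 2))
  ks <- kmeans_stability(pts, k = 2, n_rep = 40, seed = 39)
  expect_equal(bipartition_respect(ks, 1:12, 13:24), 1.0)
})

test_that("a planted two-condition design separates healthy from diseased clusters", {
  cfg <- simulation_config(groups = c("HC", "EAE"), n_blocks = 4,
                           n_probes = 800,
                           contrasts = list(D = "EAE-HC"),
                           de_prop = c(D = 0.3), effect_size = 2,
                           output_scale = "normalized", seed = 40)
  sim <- simulate_experiment(cfg)
  pr <- prcomp(t(sim$experiment$intensities))
  ks <- kmeans_stability(pr$x[, 1:2], k = 2, n_rep = 50, seed = 41)
  healthy <- sim$experiment$samples$group == "HC"
  expect_gte(bipartition_respect(ks, healthy, !healthy), 0.9)
})
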