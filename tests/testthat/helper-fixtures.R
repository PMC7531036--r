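# In-code fixtures shared across the suite.

# minimal contrast-table builder
toy_table <- function(probe_id, logFC, significant,
                      gene_id = NULL, contrast = "toy") {
  if (is.null(gene_id)) gene_id <- paste0("g_", probe_id)
  out <- data.frame(
    probe_id = as.character(probe_id), gene_id = gene_id,
    logFC = logFC, t = logFC, p_value = ifelse(significant, 1e-4, 0.5),
    adj_p_value = ifelse(significant, 1e-3, 0.6),
    significant = significant,
    direction = ifelse(logFC > 0, "up", "down"),
    stringsAsFactors = FALSE)
  class(out) <- c("contrast_table", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

# small two-group blocked experiment on the normalized scale
toy_experiment <- function(y, groups, blocks, gene_id = NULL,
                           quality = "perfect", scale = "normalized") {
  y <- matrix(y, ncol = length(groups))
  G <- nrow(y)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(G))
  expression_experiment(
    y, NULL,
    samples = data.frame(sample_id = paste0("s", seq_along(groups)),
                         group = groups, block = blocks,
                         stringsAsFactors = FALSE),
    probes = data.frame(probe_id = paste0("p", seq_len(G)),
                        gene_id = gene_id,
                        quality = rep_len(quality, G),
                        stringsAsFactors = FALSE),
    scale = scale)
}

# tiny raw-scale experiment with detection p-values
toy_raw_experiment <- function(n_probes = 3, n_samples = 2,
                               values = NULL, detection = NULL) {
  if (is.null(values))
    values <- matrix(signif(abs(rnorm(n_probes * n_samples, 100, 20)), 6),
                     n_probes)
  if (is.null(detection))
    detection <- matrix(signif(runif(n_probes * n_samples), 6), n_probes)
  expression_experiment(
    values, detection,
    samples = data.frame(sample_id = paste0("s", seq_len(n_samples)),
                         group = rep(c("A", "B"), length.out = n_samples),
                         block = rep("b1", n_samples),
                         stringsAsFactors = FALSE),
    probes = data.frame(probe_id = paste0("p", seq_len(n_probes)),
                        gene_id = paste0("g", seq_len(n_probes)),
                        quality = "good", stringsAsFactors = FALSE),
    scale = "raw")
}

expect_identical_experiment <- function(a, b, tol = 0) {
  expect_equal(a$intensities, b$intensities, tolerance = tol)
  if (!is.null(a$detection_p) || !is.null(b$detection_p))
    expect_equal(a$detection_p, b$detection_p, tolerance = tol)
  expect_equal(a$samples$sample_id, b$samples$sample_id)
  expect_equal(a$samples$group, b$samples$group)
  expect_equal(as.character(a$samples$block), as.character(b$samples$block))
  expect_equal(a$probes$probe_id, b$probes$probe_id)
  expect_equal(a$probes$gene_id, b$probes$gene_id)
  expect_equal(a$probes$quality, b$probes$quality)
  expect_equal(a$scale, b$scale)
}
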