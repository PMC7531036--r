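# Gene-set principal-component disease scoring and k-means partition
# stability.

#' Principal-component scores of a gene set's transcripts
#'
#' PCA of the samples x selected-transcripts submatrix on the covariance
#' scale (variables centered, not scaled). Scores are standardized to unit
#' variance for display, and each component's orientation is fixed so the
#' sum of its loadings is positive, making the sign deterministic.
#'
#' @param x a normalized [expression_experiment].
#' @param gene_set character vector of gene ids; all probes of member
#'   genes are selected.
#' @param n_components number of components to return.
#' @return a `pc_score_result`: list with `scores` (samples x components,
#'   unit variance), `scores_raw`, `var_explained` (fractions), `loadings`,
#'   `n_probes`, `flipped` (logical per component).
#' @export
geneset_pc_scores <- function(x, gene_set, n_components = 2) {
  idx <- which(x$probes$gene_id %in% gene_set)
  if (length(idx) < 2) {
    missing <- setdiff(gene_set, x$probes$gene_id)
    stop("fewer than 2 member probes on the platform; missing gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  M <- t(x$intensities[idx, , drop = FALSE])
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  var_explained <- pr$sdev^2 / sum(pr$sdev^2)
  flipped <- logical(k)
  scores_raw <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(loadings[, j]) < 0) {
      scores_raw[, j] <- -scores_raw[, j]
      loadings[, j] <- -loadings[, j]
      flipped[j] <- TRUE
    }
  }
  sds <- apply(scores_raw, 2, stats::sd)
  scores <- sweep(scores_raw, 2, ifelse(sds > 0, sds, 1), "/")
  structure(list(scores = scores, scores_raw = scores_raw,
                 var_explained = var_explained[seq_len(k)],
                 var_explained_all = var_explained,
                 loadings = loadings, n_probes = length(idx),
                 flipped = flipped,
                 sample_id = x$samples$sample_id,
                 group = x$samples$group),
            class = "pc_score_result")
}

#' @export
print.pc_score_result <- function(x, ...) {
  cat("pc_score_result:", length(x$sample_id), "samples,",
      x$n_probes, "probes; variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Compare first-component scores of each group against pooled controls
#'
#' One two-sided two-sample test per non-control group versus the pooled
#' control samples, with multiple-testing adjustment across comparisons.
#' Significance stars follow the usual figure-caption convention:
#' `***` adjusted p < 0.001, `*` adjusted p < 0.05, else `n.s.`.
#'
#' @param scores numeric vector of per-sample scores (e.g. PC1).
#' @param groups group label per sample.
#' @param control_groups labels pooled as the control condition.
#' @param test `"welch"` (Welch's t) or `"wilcoxon"`.
#' @param adjust `"BH"`, `"holm"` or `"none"`.
#' @return data.frame: `group`, `n`, `mean_diff`, `statistic`, `p_value`,
#'   `adj_p_value`, `stars`. Groups with fewer than 2 samples are skipped
#'   with a warning.
#' @export
compare_score_groups <- function(scores, groups, control_groups,
                                 test = c("welch", "wilcoxon"),
                                 adjust = c("BH", "holm", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  ctrl <- scores[groups %in% control_groups]
  if (length(ctrl) < 2) stop("fewer than 2 pooled control samples")
  rows <- list()
  for (g in setdiff(unique(groups), control_groups)) {
    v <- scores[groups == g]
    if (length(v) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    ht <- if (test == "welch") stats::t.test(v, ctrl)
          else stats::wilcox.test(v, ctrl, exact = FALSE)
    rows[[g]] <- data.frame(group = g, n = length(v),
                            mean_diff = mean(v) - mean(ctrl),
                            statistic = unname(ht$statistic),
                            p_value = ht$p.value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p_value <- stats::p.adjust(out$p_value,
                                     method = if (adjust == "BH") "BH" else
                                       if (adjust == "holm") "holm" else "none")
  out$stars <- ifelse(out$adj_p_value < 0.001, "***",
                      ifelse(out$adj_p_value < 0.05, "*", "n.s."))
  out
}

# canonical form of a partition: clusters relabeled in order of their
# smallest member index
canonical_partition <- function(labels) {
  first_seen <- match(unique(labels), labels)
  relabel <- order(order(first_seen))
  new <- integer(length(labels))
  for (i in seq_along(unique(labels)))
    new[labels == unique(labels)[i]] <- relabel[i]
  new
}

#' Stability of k-means clustering over random restarts
#'
#' Runs k-means `n_rep` times with random initialization, canonicalizes
#' each partition label-invariantly (clusters numbered by smallest member
#' index), and aggregates identical partitions. The modal (most frequent)
#' partition is the stable clustering solution.
#'
#' @param features numeric matrix, samples x features (e.g. the first two
#'   display PCs of the expression matrix).
#' @param k number of clusters.
#' @param n_rep number of random restarts.
#' @param seed master seed.
#' @return a `kmeans_stability` list: `records` (data.frame `partition`,
#'   `freq`, `tot_withinss`), `modal` (label vector), `modal_freq`,
#'   `n_rep`, `partitions` (one canonical label vector per repeat).
#' @export
kmeans_stability <- function(features, k = 4, n_rep = 100, seed = NULL) {
  features <- as.matrix(features)
  if (k > nrow(features))
    stop("k = ", k, " exceeds the number of samples (", nrow(features), ")")
  partitions <- vector("list", n_rep)
  withinss <- numeric(n_rep)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      km <- stats::kmeans(features, centers = k, nstart = 1)
      partitions[[r]] <- canonical_partition(km$cluster)
      withinss[r] <- km$tot.withinss
    }
  })
  keys <- vapply(partitions, paste, character(1), collapse = ",")
  tab <- sort(table(keys), decreasing = TRUE)
  records <- data.frame(
    partition = names(tab),
    freq = as.integer(tab),
    tot_withinss = vapply(names(tab), function(kk)
      mean(withinss[keys == kk]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  modal <- as.integer(strsplit(records$partition[1], ",")[[1]])
  structure(list(records = records, modal = modal,
                 modal_freq = records$freq[1], n_rep = n_rep,
                 partitions = partitions),
            class = "kmeans_stability")
}

#' @export
print.kmeans_stability <- function(x, ...) {
  cat("kmeans_stability:", nrow(x$records), "distinct partition(s) over",
      x$n_rep, "repeats; modal frequency", x$modal_freq, "/", x$n_rep, "\n")
  invisible(x)
}

#' Fraction of repeats respecting a sample bipartition
#'
#' A repeat respects the bipartition when no cluster contains samples from
#' both sides (e.g. all healthy groups separated from all diseased
#' groups).
#'
#' @param x a `kmeans_stability` result, or a list of partition label
#'   vectors.
#' @param side_a,side_b integer sample indices (or logical masks) of the
#'   two sides.
#' @return the fraction of repeats in `[0, 1]`.
#' @export
bipartition_respect <- function(x, side_a, side_b) {
  partitions <- if (inherits(x, "kmeans_stability")) x$partitions else x
  if (is.logical(side_a)) side_a <- which(side_a)
  if (is.logical(side_b)) side_b <- which(side_b)
  ok <- vapply(partitions, function(lab) {
    length(intersect(unique(lab[side_a]), unique(lab[side_b]))) == 0
  }, logical(1))
  mean(ok)
}
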