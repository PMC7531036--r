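#' Configuration for the synthetic expression-experiment generator
#'
#' The generator emulates a randomized block microarray design: groups of
#' animals (or cell types) hybridized across a small number of chips/pools,
#' with a shared additive block effect on the log scale (compound
#' symmetry), per-probe residual variances drawn from a scaled
#' inverse-chi-square prior (so the empirical-Bayes moderation
#' hyperparameters are recoverable by construction), and a raw scale with
#' additive background plus multiplicative noise, so that raw-scale
#' variance grows with the mean.
#'
#' `sigma_block` is expressed in units of the probe's residual standard
#' deviation, which makes the implied within-block correlation
#' `rho = sigma_block^2 / (1 + sigma_block^2)` identical across probes;
#' see [sigma_block_for_rho].
#'
#' @param groups character vector of group labels. With
#'   `layout = "crossed"` each block carries one sample per group.
#' @param group_counts named integer vector of per-group sample counts
#'   (used with `layout = "counts"`, samples distributed round-robin over
#'   blocks).
#' @param n_blocks number of blocks (chips or pools), `>= 2`.
#' @param layout `"crossed"` or `"counts"`.
#' @param n_probes number of probes G.
#' @param two_probe_frac fraction of genes represented by two probes
#'   (the rest have one).
#' @param baseline_mean,baseline_sd baseline log2-intensity distribution.
#' @param prop_unexpressed fraction of probes carrying no signal
#'   (background only).
#' @param sigma_block block-effect sd in units of residual sd.
#' @param d0,s0sq residual-variance prior: per-probe variance is drawn as
#'   `s0sq * d0 / chisq(d0)` (scaled inverse-chi-square).
#' @param contrasts named list of contrast strings `"A-B"`.
#' @param de_prop per-contrast fraction of genes planted as differentially
#'   expressed; scalar (recycled) or named by contrast.
#' @param effect_size magnitude of planted log2 fold-changes.
#' @param effect_dist `"fixed"` (all magnitudes equal `effect_size`) or
#'   `"exponential"` (mean `effect_size`).
#' @param bg_mean,bg_sd additive raw-scale background distribution.
#' @param mult_sd sd of log-normal multiplicative raw-scale noise
#'   (natural-log scale).
#' @param quality_probs probabilities of the four probe-quality labels.
#' @param output_scale `"raw"` (additive background + multiplicative noise
#'   applied to the exponentiated log2 signal, with detection p-values) or
#'   `"normalized"` (the log2-scale signal itself, for exercising the
#'   model-based stages directly without the measurement layer).
#' @param seed master seed; subordinate generators are derived by fixed
#'   per-stage offsets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(groups = c("WT", "OSE0", "OSE1", "OSE4", "CFA", "MOG4"),
                              group_counts = NULL,
                              n_blocks = 4,
                              layout = c("crossed", "counts"),
                              n_probes = 5000,
                              two_probe_frac = 0.2,
                              baseline_mean = 7, baseline_sd = 1.5,
                              prop_unexpressed = 0.1,
                              sigma_block = 0.5,
                              d0 = 4, s0sq = 0.05,
                              contrasts = list(OSE4_OSE0 = "OSE4-OSE0",
                                               MOG4_CFA = "MOG4-CFA",
                                               OSE1_OSE0 = "OSE1-OSE0",
                                               CFA_WT = "CFA-WT",
                                               OSE0_WT = "OSE0-WT",
                                               OSE4_WT = "OSE4-WT"),
                              de_prop = c(OSE4_OSE0 = 0.1, MOG4_CFA = 0.1,
                                          OSE1_OSE0 = 0.1, CFA_WT = 0,
                                          OSE0_WT = 0, OSE4_WT = 0),
                              effect_size = 1.0,
                              effect_dist = c("fixed", "exponential"),
                              bg_mean = 60, bg_sd = 5,
                              mult_sd = 0.05,
                              quality_probs = c(perfect = 0.7, good = 0.2,
                                                bad = 0.05, no_match = 0.05),
                              output_scale = c("raw", "normalized"),
                              seed = 1L) {
  layout <- match.arg(layout)
  effect_dist <- match.arg(effect_dist)
  output_scale <- match.arg(output_scale)
  if (layout == "counts" && is.null(group_counts))
    stop("layout = 'counts' requires group_counts")
  if (!is.null(group_counts)) {
    layout <- "counts"
    groups <- names(group_counts)
  }
  cfg <- list(groups = groups, group_counts = group_counts,
              n_blocks = as.integer(n_blocks), layout = layout,
              n_probes = as.integer(n_probes),
              two_probe_frac = two_probe_frac,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              prop_unexpressed = prop_unexpressed,
              sigma_block = sigma_block, d0 = d0, s0sq = s0sq,
              contrasts = contrasts,
              de_prop = de_prop, effect_size = effect_size,
              effect_dist = effect_dist,
              bg_mean = bg_mean, bg_sd = bg_sd, mult_sd = mult_sd,
              quality_probs = quality_probs, output_scale = output_scale,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default configuration for the T-helper-cell experiment
#'
#' 18 samples from 4 pools (blocks): 4 naive TH0, 7 TH1, 7 TH17, with the
#' pools playing the role the chips play in the spinal-cord design.
#'
#' @param ... overrides passed to [simulation_config].
#' @return a `simulation_config`.
#' @export
th_simulation_config <- function(...) {
  args <- list(...)
  defaults <- list(group_counts = c(TH0 = 4L, TH1 = 7L, TH17 = 7L),
                   layout = "counts", n_blocks = 4,
                   contrasts = list(TH1_TH0 = "TH1-TH0",
                                    TH17_TH0 = "TH17-TH0"),
                   de_prop = c(TH1_TH0 = 0.1, TH17_TH0 = 0.1))
  do.call(simulation_config, utils::modifyList(defaults, args))
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_blocks < 2) stop("n_blocks must be >= 2")
  if (cfg$d0 <= 0) stop("d0 must be > 0")
  if (cfg$s0sq <= 0) stop("s0sq must be > 0")
  if (cfg$sigma_block < 0) stop("sigma_block must be >= 0")
  if (any(cfg$de_prop < 0 | cfg$de_prop > 1))
    stop("de_prop must lie in [0, 1]")
  if (!is.null(names(cfg$de_prop))) {
    unknown <- setdiff(names(cfg$de_prop), names(cfg$contrasts))
    if (length(unknown))
      stop("de_prop names not among contrasts: ",
           paste(unknown, collapse = ", "))
  }
  if (cfg$prop_unexpressed < 0 || cfg$prop_unexpressed >= 1)
    stop("prop_unexpressed must lie in [0, 1)")
  invisible(cfg)
}

#' Block-effect scale for a target within-block correlation
#' @param rho target within-block correlation in `[0, 1)`.
#' @return the `sigma_block` value (units of residual sd) implying `rho`.
#' @export
sigma_block_for_rho <- function(rho) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  sqrt(rho / (1 - rho))
}

# sample layout implied by a config: data.frame sample_id/group/block
sample_layout <- function(cfg) {
  if (cfg$layout == "crossed") {
    df <- expand.grid(group = cfg$groups,
                      block = paste0("b", seq_len(cfg$n_blocks)),
                      stringsAsFactors = FALSE)
  } else {
    rows <- list()
    for (g in names(cfg$group_counts)) {
      n <- cfg$group_counts[[g]]
      blocks <- paste0("b", rep(seq_len(cfg$n_blocks), length.out = n))
      rows[[g]] <- data.frame(group = g, block = blocks,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
  }
  df$sample_id <- paste0("s", seq_len(nrow(df)), "_", df$group, "_", df$block)
  df[, c("sample_id", "group", "block")]
}

# gene-to-probe map: ids plus expressed flag and quality labels
probe_annotation <- function(cfg) {
  G <- cfg$n_probes
  f2 <- cfg$two_probe_frac
  g2 <- floor(G * f2 / (1 + f2))
  g1 <- G - 2 * g2
  n_genes <- g1 + g2
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  gene_of_probe <- c(gene_ids[seq_len(g1)],
                     rep(gene_ids[g1 + seq_len(g2)], each = 2))
  gene_of_probe <- sample(gene_of_probe)  # scatter duplicates over the chip
  data.frame(probe_id = sprintf("P%05d", seq_len(G)),
             gene_id = gene_of_probe,
             quality = sample(names(cfg$quality_probs), G, replace = TRUE,
                              prob = cfg$quality_probs),
             stringsAsFactors = FALSE)
}

#' Simulate a blocked expression experiment with ground truth
#'
#' Log2-scale signal = baseline + group effect + block effect + residual;
#' raw intensity = additive background + multiplicative-noise-scaled
#' exponentiated signal. Detection p-values are the upper-tail probability
#' of the background distribution at the observed raw intensity: small for
#' probes whose signal exceeds background and approximately uniform for
#' background-only probes. Differential expression is planted at the gene
#' level (all probes of a planted gene carry the same signed shift) on the
#' positive-coefficient group of each configured contrast.
#'
#' @param cfg a [simulation_config].
#' @return a list with elements `experiment` (a raw-scale
#'   [expression_experiment]) and `truth` (a `synthetic_truth` list:
#'   per-probe per-contrast true log2 fold-changes and DE indicators,
#'   per-probe residual variances, the implied block correlation
#'   `rho_true`, the prior parameters, per-contrast DE gene lists, and the
#'   expressed-probe flags).
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  with_seed(derive_seed(cfg$seed, 101L), simulate_experiment_impl(cfg))
}

#' Simulate the T-helper-cell experiment
#' @param cfg a [simulation_config]; defaults to [th_simulation_config].
#' @return as [simulate_experiment].
#' @export
simulate_th_experiment <- function(cfg = th_simulation_config()) {
  simulate_experiment(cfg)
}

simulate_experiment_impl <- function(cfg) {
  layout <- sample_layout(cfg)
  probes <- probe_annotation(cfg)
  G <- cfg$n_probes
  n <- nrow(layout)
  groups <- cfg$groups
  blocks <- unique(layout$block)

  sigma2 <- cfg$s0sq * cfg$d0 / stats::rchisq(G, cfg$d0)
  baseline <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  expressed <- if (cfg$output_scale == "raw")
    stats::runif(G) >= cfg$prop_unexpressed else rep(TRUE, G)

  # plant gene-level effects on the +1 group of each contrast
  de_prop <- cfg$de_prop
  if (is.null(names(de_prop)))
    de_prop <- stats::setNames(rep_len(de_prop, length(cfg$contrasts)),
                               names(cfg$contrasts))
  beta <- matrix(0, G, length(groups), dimnames = list(probes$probe_id, groups))
  genes <- unique(probes$gene_id)
  de_genes <- list()
  for (cn in names(cfg$contrasts)) {
    pi_c <- if (cn %in% names(de_prop)) de_prop[[cn]] else 0
    cvec <- as_contrast_vector(cfg$contrasts[[cn]], groups)
    hit <- genes[stats::runif(length(genes)) < pi_c]
    de_genes[[cn]] <- hit
    if (!length(hit)) next
    mag <- switch(cfg$effect_dist,
                  fixed = rep(cfg$effect_size, length(hit)),
                  exponential = stats::rexp(length(hit), 1 / cfg$effect_size))
    delta <- stats::setNames(mag * sample(c(-1, 1), length(hit), replace = TRUE),
                             hit)
    idx <- probes$gene_id %in% hit
    pos_group <- names(cvec)[cvec > 0][1]
    beta[idx, pos_group] <- beta[idx, pos_group] + delta[probes$gene_id[idx]]
  }

  # log2-scale signal with compound-symmetric block effect
  sd_g <- sqrt(sigma2)
  block_eff <- matrix(stats::rnorm(G * length(blocks), 0, 1), G) *
    (cfg$sigma_block * sd_g)
  colnames(block_eff) <- blocks
  gidx <- match(layout$group, groups)
  bidx <- match(layout$block, blocks)
  y <- baseline + beta[, gidx, drop = FALSE] +
    block_eff[, bidx, drop = FALSE] +
    matrix(stats::rnorm(G * n, 0, 1), G, n) * sd_g

  if (cfg$output_scale == "normalized") {
    exp_obj <- expression_experiment(y, NULL, layout, probes,
                                     scale = "normalized")
  } else {
    signal <- ifelse(expressed, 1, 0) * 2^y
    bg <- matrix(stats::rnorm(G * n, cfg$bg_mean, cfg$bg_sd), G, n)
    mult <- exp(matrix(stats::rnorm(G * n, 0, cfg$mult_sd), G, n))
    raw <- pmax(bg + signal * mult, 0)
    detection_p <- stats::pnorm(raw, cfg$bg_mean, cfg$bg_sd, lower.tail = FALSE)
    exp_obj <- expression_experiment(raw, detection_p, layout, probes,
                                     scale = "raw")
  }

  con_mat <- do.call(rbind, lapply(cfg$contrasts, as_contrast_vector, groups))
  true_lfc <- beta %*% t(con_mat)
  colnames(true_lfc) <- names(cfg$contrasts)
  de <- abs(true_lfc) > 1e-12
  truth <- structure(list(
    true_lfc = true_lfc, de = de, sigma2 = sigma2,
    rho_true = cfg$sigma_block^2 / (1 + cfg$sigma_block^2),
    sigma_block = cfg$sigma_block, d0 = cfg$d0, s0sq = cfg$s0sq,
    expressed = expressed,
    gene_map = probes[, c("probe_id", "gene_id")],
    de_genes = de_genes, config = cfg
  ), class = "synthetic_truth")

  list(experiment = exp_obj, truth = truth)
}

#' Plant a gene set with controlled enrichment for differential expression
#'
#' Every gene in the universe (genes with at least one expressed probe) is
#' included with a Bernoulli probability whose odds are `omega`-fold higher
#' for genes differentially expressed in `contrast` than for the rest,
#' renormalized so the expected set size is `set_size`. `omega = 1` yields
#' uniform inclusion; `omega = Inf` samples `set_size` genes from the DE
#' genes only.
#'
#' @param truth a `synthetic_truth` from [simulate_experiment].
#' @param contrast contrast name in the truth.
#' @param set_size expected number of member genes K.
#' @param omega enrichment odds ratio, `> 0` (may be `Inf`).
#' @param seed RNG seed.
#' @param name set name in the returned collection.
#' @return a [gene_set_collection] with one set.
#' @export
plant_gene_set <- function(truth, contrast, set_size, omega, seed = 1L,
                           name = "planted") {
  universe <- unique(truth$gene_map$gene_id[truth$expressed])
  if (set_size > length(universe))
    stop("set_size exceeds the gene universe (", length(universe), ")")
  if (omega <= 0) stop("omega must be > 0")
  if (!contrast %in% colnames(truth$de))
    stop("unknown contrast: ", contrast)
  de_genes <- intersect(truth$de_genes[[contrast]], universe)
  n_de <- length(de_genes)
  n_non <- length(universe) - n_de

  members <- with_seed(seed, {
    if (is.infinite(omega)) {
      if (set_size > n_de)
        stop("omega = Inf requires set_size <= number of DE genes (", n_de, ")")
      sample(de_genes, set_size)
    } else {
      # p_non = q, p_de = omega*q / (1 - q + omega*q); expected size K
      f <- function(q) n_de * omega * q / (1 - q + omega * q) + n_non * q - set_size
      q <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
      p <- ifelse(universe %in% de_genes, omega * q / (1 - q + omega * q), q)
      universe[stats::runif(length(universe)) < p]
    }
  })
  gene_set_collection(stats::setNames(list(members), name),
                      stats::setNames(sprintf("planted omega=%g K=%d contrast=%s",
                                              omega, as.integer(set_size), contrast),
                                      name))
}
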