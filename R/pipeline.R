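# End-to-end orchestration: simulate (or load) -> preprocess -> blocked
# moderated-t DE -> directional sets -> permutation enrichment -> PC
# scoring and clustering stability -> paired binomial tests, with all
# artifacts written under one output directory.

#' Default pipeline configuration
#'
#' Defaults mirror the study design the package emulates: 100,000
#' permutations, k = 4 clusters over 100 restarts, 10 principal components
#' in the batch check, detection cutoff 0.05 with 90% detected fraction,
#' consensus trim fraction 0.15 (a package default).
#'
#' @return a nested list; override entries via the `config` argument of
#'   [run_pipeline] (or a YAML file with the same structure).
#' @export
default_pipeline_config <- function() {
  list(
    experiment = "eae",           # "eae" or "th"
    sim = list(),                 # overrides for simulation_config()
    inputs = NULL,                # list(matrix, samples, probes, detection,
                                  #      dialect, gmt) to analyze real data
    detect_alpha = 0.05,
    detected_fraction = 0.9,
    drop_quality = c("bad", "no_match"),
    n_pcs = 10,
    alpha = 0.05,
    adjust = "BH",
    trim = 0.15,
    n_perm = 100000,
    enrich_adjust = "holm",
    planted_sets = list(
      risk = list(contrast = "OSE4_OSE0", size = 551, omega = 3),
      null = list(contrast = "OSE4_OSE0", size = 300, omega = 1)
    ),
    score_set = "risk",
    k = 4,
    n_rep = 100,
    healthy_groups = c("WT", "OSE0", "CFA"),
    set_defs = list(ose4 = "OSE4_OSE0", mog4 = "MOG4_CFA",
                    ose1 = "OSE1_OSE0",
                    controls = c("CFA_WT", "OSE0_WT"))
  )
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' @param config `NULL` (defaults), a list of overrides, or the path of a
#'   YAML file; see [default_pipeline_config].
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory; all stage TSVs, `summary.json` and
#'   `manifest.json` are written there.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config %||% list())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  input_hashes <- NULL

  # --- data ---------------------------------------------------------------
  truth <- NULL
  collections <- NULL
  if (is.null(cfg$inputs)) {
    sim <- with_stage("simulate", {
      base <- if (identical(cfg$experiment, "th")) th_simulation_config()
              else simulation_config()
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(base[setdiff(names(base), "layout")],
                                           c(cfg$sim,
                                             list(seed = derive_seed(seed, 11L)))))
      simulate_experiment(sim_cfg)
    })
    raw <- sim$experiment
    truth <- sim$truth
    collections <- with_stage("plant_gene_sets", {
      sets <- list(); prov <- character(0)
      i <- 0L
      for (nm in names(cfg$planted_sets)) {
        ps <- cfg$planted_sets[[nm]]
        i <- i + 1L
        gs <- plant_gene_set(truth, ps$contrast, ps$size, ps$omega,
                             seed = derive_seed(seed, 20L + i), name = nm)
        sets[[nm]] <- gs$sets[[nm]]
        prov[nm] <- gs$provenance[[nm]]
      }
      gene_set_collection(sets, prov)
    })
  } else {
    raw <- with_stage("read_inputs", {
      read_expression(cfg$inputs$matrix, cfg$inputs$samples,
                      cfg$inputs$probes,
                      detection_path = cfg$inputs$detection,
                      dialect = cfg$inputs$dialect %||% "separate")
    })
    collections <- with_stage("read_gene_sets", read_gmt(cfg$inputs$gmt))
    input_hashes <- as.list(tools::md5sum(unlist(
      cfg$inputs[c("matrix", "samples", "probes", "detection", "gmt")],
      use.names = TRUE)))
  }

  # --- preprocess ---------------------------------------------------------
  pre <- with_stage("preprocess", {
    det <- filter_probes(raw, detect_alpha = cfg$detect_alpha,
                         detected_fraction = cfg$detected_fraction,
                         drop_quality = character(0))
    norm <- vst_transform(det)
    norm <- norm[!(norm$probes$quality %in% cfg$drop_quality), ]
    norm
  })
  batch <- with_stage("batch_association",
                      batch_association(pre, n_pcs = cfg$n_pcs))

  # --- differential expression -------------------------------------------
  contrasts <- if (!is.null(truth)) truth$config$contrasts
               else cfg$contrasts %||%
                 stop("config$contrasts required for user-supplied inputs")
  design <- design_spec(pre$samples$group, pre$samples$block, contrasts)
  de <- with_stage("linear_de",
                   run_de(pre, design, adjust = cfg$adjust,
                          alpha = cfg$alpha, trim = cfg$trim))

  # --- set algebra --------------------------------------------------------
  sd_ <- cfg$set_defs
  eae_ok <- all(c(sd_$ose4, sd_$mog4, sd_$ose1, sd_$controls) %in%
                  names(de$tables))
  sets <- venn <- NULL
  if (eae_ok) {
    sets <- with_stage("set_algebra",
                       define_analysis_sets(de$tables, ose4 = sd_$ose4,
                                            mog4 = sd_$mog4, ose1 = sd_$ose1,
                                            controls = sd_$controls))
    venn <- directional_venn(de$tables[c(sd_$ose4, sd_$mog4, sd_$ose1)])
  } else if (all(c("TH1_TH0", "TH17_TH0") %in% names(de$tables))) {
    sets <- with_stage("set_algebra", define_th_sets(de$tables))
    venn <- directional_venn(de$tables[c("TH1_TH0", "TH17_TH0")])
  }

  # --- enrichment ---------------------------------------------------------
  universe <- unique(pre$probes$gene_id[!is.na(pre$probes$gene_id)])
  enrich <- NULL
  if (!is.null(sets))
    enrich <- with_stage("enrichment",
                         run_enrichment_suite(sets, collections, universe,
                                              n_perm = cfg$n_perm,
                                              seed = derive_seed(seed, 31L),
                                              adjust = cfg$enrich_adjust))

  # --- scoring and clustering --------------------------------------------
  score_genes <- collections$sets[[cfg$score_set]] %||% collections$sets[[1]]
  scores <- with_stage("geneset_pc_scores",
                       geneset_pc_scores(pre, score_genes, n_components = 2))
  healthy <- intersect(cfg$healthy_groups, unique(pre$samples$group))
  comparisons <- NULL
  if (length(healthy) && length(setdiff(unique(pre$samples$group), healthy)))
    comparisons <- with_stage("compare_score_groups",
                              compare_score_groups(scores$scores[, 1],
                                                   pre$samples$group, healthy))
  full_pr <- stats::prcomp(t(pre$intensities), center = TRUE, scale. = FALSE)
  feat <- sweep(full_pr$x[, 1:2, drop = FALSE], 2,
                apply(full_pr$x[, 1:2, drop = FALSE], 2, stats::sd), "/")
  km <- with_stage("kmeans_stability",
                   kmeans_stability(feat, k = min(cfg$k, nrow(feat)),
                                    n_rep = cfg$n_rep,
                                    seed = derive_seed(seed, 41L)))
  biparts <- NULL
  if (length(healthy)) {
    side_a <- pre$samples$group %in% healthy
    biparts <- bipartition_respect(km, side_a, !side_a)
  }

  # --- paired tests -------------------------------------------------------
  paired <- NULL
  if (eae_ok) {
    paired <- with_stage("paired_tests", {
      res <- list(
        magnitude_ose4_vs_ose1_all =
          magnitude_binomial(de$tables[[sd_$ose4]], de$tables[[sd_$ose1]], "all"),
        magnitude_ose4_vs_mog4_all =
          magnitude_binomial(de$tables[[sd_$ose4]], de$tables[[sd_$mog4]], "all")
      )
      de_both <- tryCatch(
        magnitude_binomial(de$tables[[sd_$ose4]], de$tables[[sd_$ose1]],
                           "de_in_both"),
        error = function(e) NULL)
      if (!is.null(de_both)) res$magnitude_ose4_vs_ose1_de <- de_both
      dircon <- tryCatch(
        direction_consistency(de$tables[[sd_$ose4]], de$tables[[sd_$ose1]]),
        error = function(e) NULL)
      if (!is.null(dircon)) res$direction_ose4_vs_ose1 <- dircon
      res
    })
  }

  # --- outputs ------------------------------------------------------------
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (cn in names(de$tables)) wt(de$tables[[cn]], paste0("de_", cn, ".tsv"))
  wt(batch, "batch_association.tsv")
  if (!is.null(venn)) wt(venn, "venn_regions.tsv")
  if (!is.null(sets)) {
    for (s in sets) {
      wt(data.frame(probe_id = s$probe_ids,
                    direction = unname(s$direction)),
         paste0("set_", s$name, "_probes.tsv"))
      wt(data.frame(gene_id = s$genes), paste0("set_", s$name, "_genes.tsv"))
    }
  }
  if (!is.null(enrich)) wt(enrich, "enrichment.tsv")
  wt(data.frame(sample_id = scores$sample_id, group = scores$group,
                scores$scores), "scores.tsv")
  if (!is.null(comparisons)) wt(comparisons, "score_comparisons.tsv")
  wt(km$records, "partitions.tsv")

  paired_summary <- lapply(paired, function(pt)
    list(n = pt$n, k = pt$k, proportion = pt$proportion,
         p_value = pt$p_value, log10_p = pt$log_p / log(10),
         ci = c(pt$ci_low, pt$ci_high)))
  summary <- list(
    n_probes_input = nrow(raw$intensities),
    n_probes_analyzed = nrow(pre$intensities),
    n_genes_universe = length(universe),
    rho_consensus = de$rho,
    d0 = de$params$d0, s0sq = de$params$s0sq,
    de_counts = lapply(de$tables, function(tt) sum(tt$significant)),
    set_sizes_probes = if (!is.null(sets))
      lapply(sets, function(s) length(s$probe_ids)),
    set_sizes_genes = if (!is.null(sets))
      lapply(sets, function(s) length(s$genes)),
    enrichment = enrich,
    pc1_var_explained = scores$var_explained[1],
    score_comparisons = comparisons,
    modal_partition_freq = km$modal_freq,
    n_rep = km$n_rep,
    bipartition_fraction = biparts,
    paired = paired_summary
  )
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("eaetx")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "inputs")],
    inputs = cfg$inputs,
    input_md5 = input_hashes
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", force = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(summary)
}
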