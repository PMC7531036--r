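# Directional transcript-set algebra over contrast tables: the named
# analysis sets (common disease transcripts and the contrast-specific
# sets) are boolean combinations of per-contrast significance flags, with
# direction kept as annotation rather than membership.

check_common_universe <- function(tables) {
  ids <- lapply(tables, function(tt) tt$probe_id)
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]]))
      stop("contrast tables have mismatched probe universes")
  }
  ids[[1]]
}

#' Direction-aware Venn region counts across contrasts
#'
#' Up- and downregulated transcripts are tallied separately: for each
#' direction, every probe significant in that direction in at least one
#' contrast contributes to exactly one inclusion/exclusion region. A probe
#' significant up in one contrast and down in another therefore appears in
#' both direction-specific tallies.
#'
#' @param tables named list of `contrast_table`s over a common probe
#'   universe.
#' @return data.frame with columns `direction`, `region` (contrast names
#'   joined by `&`), `count`, covering all non-empty region combinations.
#' @export
directional_venn <- function(tables) {
  check_common_universe(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(tt)
      attr(tt, "contrast") %||% "unnamed", character(1))
  k <- length(tables)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  colnames(combos) <- names(tables)
  rows <- list()
  for (dir in c("up", "down")) {
    flags <- vapply(tables, function(tt) tt$significant & tt$direction == dir,
                    logical(nrow(tables[[1]])))
    flags <- matrix(flags, ncol = k)
    key <- apply(flags, 1, function(r) paste(as.integer(r), collapse = ""))
    for (i in seq_len(nrow(combos))) {
      memb <- as.logical(combos[i, ])
      ckey <- paste(as.integer(memb), collapse = "")
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir,
        region = paste(names(tables)[memb], collapse = "&"),
        count = sum(key == ckey),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a transcript set from inclusion/exclusion significance rules
#'
#' Membership is direction-agnostic: a probe significant in any direction
#' in all `include` contrasts and in none of the `exclude` contrasts
#' belongs, and its direction in the first `include` contrast is kept as
#' annotation.
#'
#' @param tables named list of `contrast_table`s.
#' @param include contrast names the probe must be significant in.
#' @param exclude contrast names the probe must not be significant in.
#' @param name set name.
#' @return a `transcript_set`: list with `name`, `probe_ids`, `direction`,
#'   `genes` (unique non-missing gene ids), `rule`.
#' @export
boolean_set <- function(tables, include, exclude = character(0),
                        name = paste(include, collapse = "&")) {
  missing <- setdiff(c(include, exclude), names(tables))
  if (length(missing))
    stop("missing required contrast(s): ", paste(missing, collapse = ", "))
  check_common_universe(tables[c(include, exclude)])
  sig <- vapply(tables, function(tt) tt$significant,
                logical(nrow(tables[[1]])))
  keep <- rep(TRUE, nrow(tables[[1]]))
  for (cn in include) keep <- keep & sig[, cn]
  for (cn in exclude) keep <- keep & !sig[, cn]
  tt1 <- tables[[include[1]]]
  gl <- collapse_to_genes(tt1$probe_id[keep],
                          stats::setNames(tt1$gene_id, tt1$probe_id),
                          directions = stats::setNames(tt1$direction,
                                                       tt1$probe_id)[tt1$probe_id[keep]])
  structure(list(
    name = name,
    probe_ids = tt1$probe_id[keep],
    direction = stats::setNames(tt1$direction[keep], tt1$probe_id[keep]),
    genes = gl$genes,
    n_unannotated = gl$n_dropped,
    conflicted_genes = gl$conflicted,
    rule = paste0("sig(", paste(include, collapse = " & "), ")",
                  if (length(exclude))
                    paste0(" & !sig(", paste(exclude, collapse = " | "), ")"))
  ), class = "transcript_set")
}

#' Named analysis sets of the two-model EAE comparison
#'
#' Builds the five standard sets from the contrast tables:
#' * `CDT` (common disease transcripts): significant in both the
#'   spontaneous-model contrast and the induced-model contrast, but in
#'   neither control contrast;
#' * `OSE4sp`: significant in the spontaneous-model contrast only;
#' * `MOG4sp`: significant in the induced-model contrast only;
#' * `OSE1ex`: significant in the mild-disease contrast and in no control
#'   contrast;
#' * `OSE1sp`: significant in the mild-disease contrast and in no other
#'   contrast at all.
#'
#' @param tables named list of `contrast_table`s.
#' @param ose4,mog4,ose1 names of the severe-spontaneous, induced and
#'   mild-spontaneous disease contrasts.
#' @param controls names of the control contrasts.
#' @return a `transcript_set_collection`: named list of `transcript_set`s.
#' @export
define_analysis_sets <- function(tables,
                                 ose4 = "OSE4_OSE0", mog4 = "MOG4_CFA",
                                 ose1 = "OSE1_OSE0",
                                 controls = c("CFA_WT", "OSE0_WT")) {
  required <- c(ose4, mog4, ose1, controls)
  missing <- setdiff(required, names(tables))
  if (length(missing))
    stop("missing required contrast(s): ", paste(missing, collapse = ", "))
  sets <- list(
    CDT = boolean_set(tables, c(ose4, mog4), controls, name = "CDT"),
    OSE4sp = boolean_set(tables, ose4, c(mog4, controls), name = "OSE4sp"),
    MOG4sp = boolean_set(tables, mog4, c(ose4, controls), name = "MOG4sp"),
    OSE1ex = boolean_set(tables, ose1, controls, name = "OSE1ex"),
    OSE1sp = boolean_set(tables, ose1, c(ose4, mog4, controls),
                         name = "OSE1sp")
  )
  structure(sets, class = "transcript_set_collection")
}

#' Cell-type-specific transcript sets for the T-helper experiment
#'
#' @param tables named list with the two polarization contrasts.
#' @param th1,th17 contrast names.
#' @return a `transcript_set_collection` with sets `TH1sp` (significant in
#'   the TH1 contrast only), `TH17sp`, and `THcommon` (both).
#' @export
define_th_sets <- function(tables, th1 = "TH1_TH0", th17 = "TH17_TH0") {
  missing <- setdiff(c(th1, th17), names(tables))
  if (length(missing))
    stop("missing required contrast(s): ", paste(missing, collapse = ", "))
  sets <- list(
    TH1sp = boolean_set(tables, th1, th17, name = "TH1sp"),
    TH17sp = boolean_set(tables, th17, th1, name = "TH17sp"),
    THcommon = boolean_set(tables, c(th1, th17), name = "THcommon")
  )
  structure(sets, class = "transcript_set_collection")
}

#' @export
print.transcript_set_collection <- function(x, ...) {
  cat("transcript_set_collection:\n")
  for (s in x)
    cat(sprintf("  %-8s %5d probes, %5d genes   [%s]\n",
                s$name, length(s$probe_ids), length(s$genes), s$rule))
  invisible(x)
}

#' Collapse probe ids to unique gene ids
#'
#' Probes without a gene annotation are dropped (count returned);
#' duplicate probes of one gene collapse to a single gene. Genes whose
#' probes disagree in direction are flagged, not removed.
#'
#' @param probe_ids character vector of probe ids.
#' @param gene_map named character vector, probe_id -> gene_id (`NA` for
#'   unannotated probes).
#' @param directions optional named character vector, probe_id ->
#'   `"up"`/`"down"`.
#' @return list with `genes` (unique gene ids), `n_dropped` (unannotated
#'   probes), `conflicted` (genes with probes in both directions).
#' @export
collapse_to_genes <- function(probe_ids, gene_map, directions = NULL) {
  g <- gene_map[probe_ids]
  dropped <- sum(is.na(g) | g == "NA" | !nzchar(g))
  g_ok <- g[!(is.na(g) | g == "NA" | !nzchar(g))]
  conflicted <- character(0)
  if (!is.null(directions)) {
    d <- directions[probe_ids][!(is.na(g) | g == "NA" | !nzchar(g))]
    tab <- table(g_ok, d)
    if (all(c("up", "down") %in% colnames(tab)))
      conflicted <- rownames(tab)[tab[, "up"] > 0 & tab[, "down"] > 0]
  }
  if (dropped > 0)
    message("collapse_to_genes: ", dropped, " unannotated probe(s) dropped")
  list(genes = unique(unname(g_ok)), n_dropped = dropped,
       conflicted = conflicted)
}
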