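#' Expression experiment container
#'
#' Bundles a probe x sample intensity matrix with per-probe/per-sample
#' detection p-values, sample annotations (group, block, position on block)
#' and probe annotations (gene id, probe quality). Blocks are the physical
#' hybridization units -- expression chips in the spinal-cord design, mouse
#' pools in the T-helper-cell design -- and every sample must carry one.
#'
#' @param intensities numeric matrix, probes x samples. Non-negative on the
#'   raw scale; any real on the normalized scale.
#' @param detection_p optional matrix of detection p-values in `[0, 1]`,
#'   same dimensions as `intensities`. Small values mean "detected above
#'   background".
#' @param samples data.frame with columns `sample_id`, `group`, `block` and
#'   optionally `position` (position on the block; defaults to the within-
#'   block order).
#' @param probes data.frame with columns `probe_id`, `gene_id` (may be `NA`
#'   for unannotated probes) and `quality`, one of `"perfect"`, `"good"`,
#'   `"bad"`, `"no_match"`. Unknown quality labels are coerced to
#'   `"no_match"` with a warning.
#' @param scale `"raw"` or `"normalized"`.
#'
#' @return An object of class `expression_experiment`: a list with elements
#'   `intensities`, `detection_p`, `samples`, `probes`, `scale`.
#' @export
expression_experiment <- function(intensities, detection_p = NULL,
                                  samples, probes,
                                  scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) stop("intensities must be numeric")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)

  for (col in c("sample_id", "group", "block")) {
    if (is.null(samples[[col]])) stop("sample annotation lacks column '", col, "'")
  }
  if (is.null(samples$position)) {
    samples$position <- stats::ave(seq_len(nrow(samples)),
                                   samples$block, FUN = seq_along)
  }
  for (col in c("probe_id", "gene_id", "quality")) {
    if (is.null(probes[[col]])) stop("probe annotation lacks column '", col, "'")
  }
  samples$sample_id <- as.character(samples$sample_id)
  probes$probe_id <- as.character(probes$probe_id)
  probes$gene_id <- as.character(probes$gene_id)

  if (nrow(probes) != nrow(intensities))
    stop("probe annotation has ", nrow(probes), " rows but matrix has ",
         nrow(intensities))
  if (nrow(samples) != ncol(intensities))
    stop("sample annotation has ", nrow(samples), " rows but matrix has ",
         ncol(intensities), " columns")
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  if (any(is.na(samples$block)) || any(!nzchar(as.character(samples$block))))
    stop("every sample must have a block id")

  bad_q <- !(probes$quality %in% c("perfect", "good", "bad", "no_match"))
  if (any(bad_q)) {
    warning(sum(bad_q), " probe(s) with unknown quality label mapped to 'no_match'")
    probes$quality[bad_q] <- "no_match"
  }

  if (scale == "raw" && any(intensities < 0, na.rm = TRUE))
    stop("raw-scale intensities must be non-negative")

  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!all(dim(detection_p) == dim(intensities)))
      stop("detection_p dimensions do not match the intensity matrix")
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop("detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- list(probes$probe_id, samples$sample_id)
  }
  dimnames(intensities) <- list(probes$probe_id, samples$sample_id)

  structure(list(intensities = intensities, detection_p = detection_p,
                 samples = samples, probes = probes, scale = scale),
            class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat("expression_experiment: ", nrow(x$intensities), " probes x ",
      ncol(x$intensities), " samples (", x$scale, " scale)\n", sep = "")
  cat("  groups: ", paste(levels(factor(x$samples$group)), collapse = ", "), "\n",
      sep = "")
  cat("  blocks: ", length(unique(x$samples$block)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_experiment <- function(x) dim(x$intensities)

#' Subset an expression experiment by probes and/or samples
#' @param x an `expression_experiment`
#' @param i probe index (logical, integer or probe_id character)
#' @param j sample index
#' @param ... unused
#' @export
`[.expression_experiment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$probes$probe_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  expression_experiment(
    intensities = x$intensities[i, j, drop = FALSE],
    detection_p = if (!is.null(x$detection_p)) x$detection_p[i, j, drop = FALSE],
    samples = x$samples[j, , drop = FALSE],
    probes = x$probes[i, , drop = FALSE],
    scale = x$scale
  )
}

#' Read an expression experiment from TSV files
#'
#' The intensity matrix is tab-separated with `probe_id` as its first
#' column. Detection p-values are supplied either as a parallel matrix file
#' with identical layout (`dialect = "separate"`) or interleaved with the
#' intensities, GenomeStudio-style, as alternating `<sample>` /
#' `<sample>.Detection` columns (`dialect = "interleaved"`).
#'
#' @param matrix_path path to the intensity matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV
#'   (`sample_id`, `group`, `block`, optional `position`).
#' @param probe_annot_path path to the probe annotation TSV
#'   (`probe_id`, `gene_id`, `quality`).
#' @param detection_path path to the detection matrix TSV (required when
#'   `dialect = "separate"` and detection values are wanted).
#' @param dialect `"separate"` or `"interleaved"`.
#' @param scale `"raw"` (default) or `"normalized"`.
#' @return an [expression_experiment].
#' @export
read_expression <- function(matrix_path, sample_sheet_path, probe_annot_path,
                            detection_path = NULL,
                            dialect = c("separate", "interleaved"),
                            scale = "raw") {
  dialect <- match.arg(dialect)
  mat_raw <- utils::read.delim(matrix_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (anyDuplicated(mat_raw[[1]]))
    stop("duplicate probe_id in ", matrix_path)
  probe_ids <- as.character(mat_raw[[1]])
  vals <- as.matrix(mat_raw[, -1, drop = FALSE])

  detection_p <- NULL
  if (dialect == "interleaved") {
    det_cols <- grepl("\\.Detection$", colnames(vals))
    if (!any(det_cols)) stop("no '.Detection' columns found in ", matrix_path)
    detection_p <- vals[, det_cols, drop = FALSE]
    vals <- vals[, !det_cols, drop = FALSE]
    colnames(detection_p) <- sub("\\.Detection$", "", colnames(detection_p))
    if (!identical(colnames(detection_p), colnames(vals)))
      stop("interleaved detection columns do not match sample columns in ",
           matrix_path)
  } else if (!is.null(detection_path)) {
    det_raw <- utils::read.delim(detection_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    if (!identical(as.character(det_raw[[1]]), probe_ids))
      stop("probe ids in ", detection_path, " do not match ", matrix_path)
    detection_p <- as.matrix(det_raw[, -1, drop = FALSE])
    if (!identical(colnames(detection_p), colnames(vals)))
      stop("sample columns in ", detection_path, " do not match ", matrix_path)
  }

  samples <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  probes <- utils::read.delim(probe_annot_path, stringsAsFactors = FALSE)

  missing_samp <- setdiff(colnames(vals), as.character(samples$sample_id))
  if (length(missing_samp))
    stop("sample(s) ", paste(missing_samp, collapse = ", "),
         " present in ", matrix_path, " but absent from ", sample_sheet_path)
  extra_samp <- setdiff(as.character(samples$sample_id), colnames(vals))
  if (length(extra_samp))
    stop("sample(s) ", paste(extra_samp, collapse = ", "),
         " present in ", sample_sheet_path, " but absent from ", matrix_path)
  samples <- samples[match(colnames(vals), samples$sample_id), , drop = FALSE]

  if (!setequal(probes$probe_id, probe_ids) ||
      nrow(probes) != length(probe_ids))
    stop("probe ids in ", probe_annot_path, " do not match ", matrix_path)
  probes <- probes[match(probe_ids, probes$probe_id), , drop = FALSE]

  expression_experiment(vals, detection_p, samples, probes, scale = scale)
}

#' Write an expression experiment to TSV files
#'
#' Numeric values are written with 6 significant digits; identifiers
#' verbatim. The inverse of [read_expression].
#'
#' @param x an [expression_experiment].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param dialect `"separate"` (matrix + detection files) or
#'   `"interleaved"` (one matrix file with `.Detection` columns).
#' @return invisibly, a named list of the paths written.
#' @export
write_expression <- function(x, dir, prefix = "expr",
                             dialect = c("separate", "interleaved")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.tsv")),
    probes = file.path(dir, paste0(prefix, "_probes.tsv"))
  )
  fmt <- function(m) matrix(as.numeric(signif(m, 6)), nrow(m),
                            dimnames = dimnames(m))
  if (dialect == "interleaved" && !is.null(x$detection_p)) {
    vals <- fmt(x$intensities)
    det <- fmt(x$detection_p)
    colnames(det) <- paste0(colnames(det), ".Detection")
    idx <- as.vector(rbind(seq_len(ncol(vals)), ncol(vals) + seq_len(ncol(det))))
    out <- cbind(vals, det)[, idx, drop = FALSE]
    df <- data.frame(probe_id = rownames(vals), out, check.names = FALSE)
    utils::write.table(df, paths$matrix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(probe_id = rownames(x$intensities),
                     fmt(x$intensities), check.names = FALSE)
    utils::write.table(df, paths$matrix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(x$detection_p)) {
      paths$detection <- file.path(dir, paste0(prefix, "_detection.tsv"))
      dd <- data.frame(probe_id = rownames(x$detection_p),
                       fmt(x$detection_p), check.names = FALSE)
      utils::write.table(dd, paths$detection, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  utils::write.table(x$samples, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$probes, paths$probes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
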