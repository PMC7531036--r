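#' Gene-set collection
#'
#' Named sets of gene identifiers with a provenance note per set. Gene
#' identifiers are opaque strings compared case-sensitively (the analysis
#' operates on unique Entrez-style keys; any symbol-to-id mapping is the
#' caller's responsibility).
#'
#' @param sets named list of character vectors of gene ids.
#' @param provenance optional named character vector of provenance notes,
#'   one per set.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, provenance = NULL) {
  if (length(sets) && is.null(names(sets)))
    stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x$sets), "set(s)\n")
  for (nm in names(x$sets))
    cat("  ", nm, ": ", length(x$sets[[nm]]), " gene(s)\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene ids`.
#' Duplicate gene ids within a line are removed; the number removed is
#' reported via `message()`.
#'
#' @param path path to the GMT file.
#' @return a [gene_set_collection]; an empty file yields an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(stats::setNames(list(), character(0))))
  sets <- list()
  prov <- character(0)
  n_dup <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields: ", path)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    n_dup <- n_dup + sum(duplicated(genes))
    sets[[fields[[1]]]] <- unique(genes)
    prov[fields[[1]]] <- fields[[2]]
  }
  if (n_dup > 0)
    message(n_dup, " duplicate gene id(s) removed while reading ", path)
  gene_set_collection(sets, prov)
}

#' Write gene sets to a GMT file
#' @param x a [gene_set_collection].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    desc <- x$provenance[[nm]]
    if (is.na(desc) || !nzchar(desc)) desc <- "na"
    paste(c(nm, desc, x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove gene ids from every set of a collection
#'
#' Used, e.g., to drop antisense transcripts from a published risk-gene
#' list before enrichment testing. Excluding an id absent from a set is a
#' no-op; per-set before/after counts are reported via `message()`.
#'
#' @param x a [gene_set_collection].
#' @param exclude character vector of gene ids to remove.
#' @return the filtered [gene_set_collection].
#' @export
apply_exclusion <- function(x, exclude) {
  exclude <- as.character(exclude)
  out <- x
  for (nm in names(x$sets)) {
    before <- length(x$sets[[nm]])
    out$sets[[nm]] <- setdiff(x$sets[[nm]], exclude)
    removed <- before - length(out$sets[[nm]])
    message("apply_exclusion: '", nm, "' ", before, " -> ",
            length(out$sets[[nm]]), " (", removed, " removed, ",
            length(exclude) - removed, " no-op)")
  }
  out
}
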