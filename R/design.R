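#' Design specification for a blocked group-comparison experiment
#'
#' Captures the group factor, the block factor (chip or pool), and the
#' named contrasts of group means to be tested. Contrast coefficients must
#' sum to zero.
#'
#' @param group character or factor of group labels, one per sample.
#' @param block character or factor of block ids, one per sample.
#' @param contrasts named list. Each element is either a string
#'   `"A-B"` (difference of two group means) or a named numeric vector of
#'   coefficients over groups summing to zero.
#' @return an object of class `design_spec` with elements `group`, `block`,
#'   `contrasts` (named list of numeric vectors over `levels(group)`).
#' @export
design_spec <- function(group, block, contrasts = list()) {
  group <- factor(group)
  block <- factor(as.character(block))
  if (length(group) != length(block))
    stop("group and block must have the same length")
  cons <- lapply(contrasts, function(cc) as_contrast_vector(cc, levels(group)))
  if (length(cons) && is.null(names(contrasts)))
    names(cons) <- vapply(contrasts, function(cc)
      if (is.character(cc)) cc else "unnamed", character(1))
  structure(list(group = group, block = block, contrasts = cons),
            class = "design_spec")
}

#' Turn a contrast specification into a coefficient vector
#'
#' @param x a string `"A-B"` or a named numeric vector.
#' @param groups character vector of group levels.
#' @return numeric vector named by `groups`, summing to zero.
#' @export
as_contrast_vector <- function(x, groups) {
  v <- stats::setNames(numeric(length(groups)), groups)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("contrast string must have the form 'A-B': ", x)
    parts <- trimws(parts)
    missing <- setdiff(parts, groups)
    if (length(missing))
      stop("contrast '", x, "' references unknown group(s): ",
           paste(missing, collapse = ", "))
    v[parts[1]] <- 1
    v[parts[2]] <- -1
  } else if (is.numeric(x)) {
    if (is.null(names(x))) stop("numeric contrasts must be named by group")
    missing <- setdiff(names(x), groups)
    if (length(missing))
      stop("contrast references unknown group(s): ",
           paste(missing, collapse = ", "))
    v[names(x)] <- x
    if (abs(sum(v)) > 1e-8) stop("contrast coefficients must sum to zero")
  } else stop("contrast must be a string 'A-B' or a named numeric vector")
  v
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec:", length(x$group), "samples,",
      nlevels(x$group), "groups,", nlevels(x$block), "blocks\n")
  cat("  contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  invisible(x)
}

# group-means design matrix (one column per group level)
design_matrix <- function(design) {
  if (nlevels(design$group) == 1)
    return(matrix(1, length(design$group), 1,
                  dimnames = list(NULL, levels(design$group))))
  X <- stats::model.matrix(~ 0 + design$group)
  colnames(X) <- levels(design$group)
  X
}
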