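# Transcript-paired exact binomial comparisons between two contrasts:
# fold-change magnitude and direction consistency. The two-sided p-value
# follows the minimum-likelihood convention (sum of outcome probabilities
# no larger than the observed outcome's probability) and is accumulated in
# log space, so p-values far below double underflow of individual terms
# remain accurate.

# two-sided exact binomial p against 0.5, minlike convention, log-space
exact_binom_two_sided <- function(k, n, log = FALSE) {
  lp <- stats::dbinom(0:n, n, 0.5, log = TRUE)
  sel <- lp <= lp[k + 1] + 1e-7
  lpv <- min(logsumexp(lp[sel]), 0)
  if (log) lpv else exp(lpv)
}

# two-sided 95% Clopper-Pearson interval from beta quantiles
clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = low, high = high)
}

paired_result <- function(n, k, restriction, n_ties = 0L) {
  ci <- clopper_pearson(k, n)
  structure(list(
    n = n, k = k, proportion = k / n,
    p_value = exact_binom_two_sided(k, n),
    log_p = exact_binom_two_sided(k, n, log = TRUE),
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    restriction = restriction, n_ties = as.integer(n_ties)
  ), class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired binomial test (%s): k = %d / n = %d (%.3f), p = %.3g, 95%% CI [%.4f, %.4f]\n",
              x$restriction, x$k, x$n, x$proportion, x$p_value,
              x$ci_low, x$ci_high))
  if (x$n_ties > 0) cat("  ", x$n_ties, "tied pair(s) excluded\n")
  invisible(x)
}

#' Paired fold-change magnitude comparison between two contrasts
#'
#' For every common probe, scores whether the absolute log fold-change in
#' `table_a` exceeds that in `table_b`, and tests the success fraction
#' against 0.5 with a two-sided exact binomial test. Exact ties are
#' excluded from the pairing (their count is recorded).
#'
#' @param table_a,table_b `contrast_table`s over a shared probe universe.
#' @param restrict `"all"` probes, or `"de_in_both"` (probes significant
#'   in both contrasts).
#' @return a `paired_test_result`: `n` informative pairs, `k` successes
#'   (`|logFC_a| > |logFC_b|`), two-sided exact `p_value` (with `log_p`
#'   for extreme values), and the 95% Clopper-Pearson interval for the
#'   success proportion.
#' @export
magnitude_binomial <- function(table_a, table_b,
                               restrict = c("all", "de_in_both")) {
  restrict <- match.arg(restrict)
  common <- intersect(table_a$probe_id, table_b$probe_id)
  if (!length(common)) stop("no common probes between the tables")
  a <- table_a[match(common, table_a$probe_id), ]
  b <- table_b[match(common, table_b$probe_id), ]
  if (restrict == "de_in_both") {
    keep <- a$significant & b$significant
    a <- a[keep, ]; b <- b[keep, ]
  }
  ties <- abs(a$logFC) == abs(b$logFC)
  n_ties <- sum(ties)
  a <- a[!ties, ]; b <- b[!ties, ]
  n <- nrow(a)
  if (n == 0) stop("no informative pairs")
  k <- sum(abs(a$logFC) > abs(b$logFC))
  paired_result(n, k, restrict, n_ties)
}

#' Direction consistency of regulation between two contrasts
#'
#' Restricted to probes significant in both contrasts: scores whether the
#' sign of the log fold-change agrees, tests against 0.5 with the
#' two-sided exact binomial test, and reports the exact two-sided 95%
#' Clopper-Pearson interval for the agreement proportion (upper bound
#' exactly 1 and lower bound `0.025^(1/n)` when all pairs agree).
#'
#' @param table_a,table_b `contrast_table`s over a shared probe universe.
#' @return a `paired_test_result`.
#' @export
direction_consistency <- function(table_a, table_b) {
  common <- intersect(table_a$probe_id, table_b$probe_id)
  a <- table_a[match(common, table_a$probe_id), ]
  b <- table_b[match(common, table_b$probe_id), ]
  keep <- a$significant & b$significant
  if (!any(keep)) stop("no probes significant in both contrasts")
  a <- a[keep, ]; b <- b[keep, ]
  n <- nrow(a)
  k <- sum(sign(a$logFC) == sign(b$logFC))
  paired_result(n, k, "de_in_both")
}
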