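# Per-probe linear models with a random block effect handled through a
# compound-symmetry correlation shared across probes, and empirical-Bayes
# moderated t statistics.
#
# Compound symmetry makes the within-block covariance (1 - rho) I + rho J,
# whose eigenvectors do not depend on rho: the normalized one-vector
# (eigenvalue 1 + (m - 1) rho) and any orthonormal complement (eigenvalue
# 1 - rho). Rotating once into that basis turns every GLS or REML
# evaluation into a cheap weighted least squares, which is what makes
# per-probe REML over thousands of probes affordable.

# orthonormal basis for R^m whose first row is the normalized one-vector
unit_first_basis <- function(m) {
  Q <- qr.Q(qr(cbind(rep(1, m), diag(m)[, seq_len(m - 1), drop = FALSE])))
  t(Q)
}

# block-diagonal rotation for a block factor; returns the n x n matrix plus
# per-row block size and is-unit-row flag (the row whose eigenvalue is
# 1 + (m-1) rho)
block_rotation <- function(block) {
  block <- factor(block)
  n <- length(block)
  R <- matrix(0, n, n)
  row_m <- integer(n)
  row_first <- logical(n)
  r <- 0L
  for (b in levels(block)) {
    idx <- which(block == b)
    m <- length(idx)
    H <- if (m == 1) matrix(1, 1, 1) else unit_first_basis(m)
    R[r + seq_len(m), idx] <- H
    row_m[r + seq_len(m)] <- m
    row_first[r + seq_len(m)] <- c(TRUE, rep(FALSE, m - 1))
    r <- r + m
  }
  list(R = R, row_m = row_m, row_first = row_first,
       max_m = max(row_m))
}

rotation_eigenvalues <- function(rot, rho) {
  ifelse(rot$row_first, 1 + (rot$row_m - 1) * rho, 1 - rho)
}

#' Consensus intra-block correlation by per-probe REML
#'
#' For every probe, the within-block correlation of a compound-symmetry
#' covariance model (unit diagonal, `rho` off-diagonal within each chip or
#' pool) is estimated by restricted maximum likelihood, profiling out the
#' residual variance. The consensus is the hyperbolic tangent of the
#' trimmed mean (trim fraction `trim`) of the per-probe atanh estimates,
#' clamped to the admissible range; probes with (near-)constant expression
#' are dropped from the consensus. This single shared correlation is how a
#' random block effect enters the downstream generalized least squares.
#'
#' @param x a normalized [expression_experiment].
#' @param design a [design_spec].
#' @param trim trimming fraction for the consensus mean.
#' @param rho_max upper clamp of the admissible range.
#' @return the consensus correlation (scalar), with the per-probe
#'   estimates attached as attribute `"per_probe"`.
#' @export
estimate_consensus_correlation <- function(x, design, trim = 0.15,
                                           rho_max = 0.99) {
  block <- design$block
  if (nlevels(factor(block)) < 2)
    stop("only one block: no intra-block correlation; use ordinary least squares")
  X <- design_matrix(design)
  rot <- block_rotation(block)
  lo <- -1 / (rot$max_m - 1) + 1e-4
  Xs <- rot$R %*% X
  Ys <- rot$R %*% t(x$intensities)   # n x G
  n <- nrow(Xs); p <- ncol(Xs)
  if (n - p <= 0) stop("no residual degrees of freedom")

  obj <- function(rho, y) {
    lam <- rotation_eigenvalues(rot, rho)
    w <- 1 / lam
    A <- crossprod(Xs, Xs * w)
    beta <- solve(A, crossprod(Xs, w * y))
    res <- y - Xs %*% beta
    rss <- sum(w * res^2)
    if (rss <= 0) rss <- 1e-300
    (n - p) * log(rss / (n - p)) + sum(log(lam)) +
      as.numeric(determinant(A, logarithm = TRUE)$modulus)
  }

  G <- ncol(Ys)
  rho_g <- rep(NA_real_, G)
  v <- apply(x$intensities, 1, stats::var)
  usable <- which(v > 1e-12)
  for (g in usable) {
    rho_g[g] <- stats::optimize(obj, c(lo, rho_max), y = Ys[, g],
                                tol = 1e-4)$minimum
  }
  n_dropped <- G - length(usable)
  if (n_dropped > 0)
    message("estimate_consensus_correlation: ", n_dropped,
            " constant probe(s) dropped from the consensus")
  z <- atanh(pmin(pmax(rho_g[usable], lo + 1e-6), rho_max))
  consensus <- tanh(mean(z, trim = trim))
  consensus <- min(max(consensus, lo), rho_max)
  attr(consensus, "per_probe") <- rho_g
  consensus
}

#' Per-probe generalized least squares with a block correlation
#'
#' Fits the group-means model probe by probe under the block
#' compound-symmetry covariance (unit diagonal, `rho` off-diagonal within a
#' block), returning per-probe coefficients, residual variances and the
#' shared unscaled covariance of the coefficients. With `rho = 0` this is
#' ordinary least squares.
#'
#' @param x a normalized [expression_experiment].
#' @param design a [design_spec].
#' @param rho intra-block correlation (e.g. from
#'   [estimate_consensus_correlation]).
#' @return a `gls_fit`: list with `coefficients` (probes x groups),
#'   `sigma2`, `df_residual`, `cov_unscaled`, `rho`, `design`, `probes`.
#' @export
fit_gls <- function(x, design, rho = 0) {
  X <- design_matrix(design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased group(s): ",
         paste(aliased, collapse = ", "))
  }
  rot <- block_rotation(design$block)
  lo <- -1 / (rot$max_m - 1)
  if (rho <= lo || rho >= 1)
    stop("rho = ", rho, " outside the admissible range (",
         signif(lo, 3), ", 1)")
  sw <- 1 / sqrt(rotation_eigenvalues(rot, rho))
  Xstar <- (rot$R %*% X) * sw
  Ystar <- (rot$R %*% t(x$intensities)) * sw
  n <- nrow(Xstar); p <- ncol(Xstar)
  fit <- stats::lm.fit(Xstar, Ystar)
  coefs <- t(fit$coefficients)
  colnames(coefs) <- colnames(X)
  res <- as.matrix(fit$residuals)
  d <- n - p
  s2 <- colSums(res^2) / d
  structure(list(
    coefficients = coefs,
    sigma2 = unname(s2),
    df_residual = d,
    cov_unscaled = chol2inv(chol(crossprod(Xstar))),
    rho = rho,
    design = design,
    probes = x$probes
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("gls_fit:", nrow(x$coefficients), "probes,",
      ncol(x$coefficients), "groups, d =", x$df_residual,
      ", rho =", signif(x$rho, 3), "\n")
  invisible(x)
}

#' Moderation hyperparameters
#' @param d0 prior degrees of freedom (> 0, may be `Inf`).
#' @param s0sq prior variance (> 0).
#' @return a `moderation_params` list.
#' @export
moderation_params <- function(d0, s0sq) {
  if (d0 <= 0) stop("d0 must be > 0")
  if (s0sq <= 0) stop("s0sq must be > 0")
  structure(list(d0 = d0, s0sq = s0sq), class = "moderation_params")
}

#' Estimate the variance prior across probes
#'
#' Under a scaled inverse-chi-square prior, the observed residual variances
#' follow `s0sq * F(d, d0)`. The hyperparameters are estimated by matching
#' the empirical mean and variance of `log(s2)` to their theoretical
#' values: the excess variance beyond `trigamma(d/2)` identifies
#' `trigamma(d0/2)`, inverted by monotone Newton root-finding, and the mean
#' then identifies `s0sq`. If the method-of-moments excess variance is
#' non-positive, `d0 = Inf` and `s0sq` is the geometric mean of the
#' variances.
#'
#' @param fit a `gls_fit` from [fit_gls] (or any list with `sigma2` and
#'   `df_residual`).
#' @return a [moderation_params] with fields `d0` and `s0sq`.
#' @export
moderate <- function(fit) {
  s2 <- fit$sigma2
  d <- fit$df_residual
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10)
    stop("fewer than 10 usable probes: hyperparameters unidentifiable")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(mean(log(s2[ok])))
  }
  structure(list(d0 = d0, s0sq = s0sq), class = "moderation_params")
}

#' Moderated t-tests for one contrast
#'
#' Shrinks each probe's residual variance toward the prior,
#' `s2_post = (d0 s0sq + d s2) / (d0 + d)`, forms the moderated t statistic
#' `logFC / (u * sqrt(s2_post))` and two-sided p-values on `d0 + d` degrees
#' of freedom (normal when `d0 = Inf`; `d0 = 0` gives the ordinary
#' t-test). P-values are adjusted within the contrast.
#'
#' @param fit a `gls_fit`.
#' @param params a [moderation_params] (from [moderate]); a list with
#'   `d0 = 0` disables moderation.
#' @param contrast a contrast name from the design, a string `"A-B"`, or a
#'   named numeric vector over groups.
#' @param adjust `"BH"`, `"holm"` or `"none"`.
#' @param alpha significance cutoff on the adjusted p-value.
#' @return a `contrast_table` data.frame: `probe_id`, `gene_id`, `logFC`
#'   (log2), `t`, `p_value`, `adj_p_value`, `significant`, `direction`.
#' @export
contrast_tests <- function(fit, params, contrast,
                           adjust = c("BH", "holm", "none"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  groups <- colnames(fit$coefficients)
  cname <- NULL
  if (is.character(contrast) && length(contrast) == 1 &&
      contrast %in% names(fit$design$contrasts)) {
    cname <- contrast
    cvec <- fit$design$contrasts[[contrast]]
  } else {
    cvec <- tryCatch(as_contrast_vector(contrast, groups),
                     error = function(e)
                       stop("contrast not in design: ", conditionMessage(e)))
    cname <- if (is.character(contrast)) contrast else "custom"
  }
  if (length(cvec) != length(groups))
    stop("contrast length does not match the design groups")
  lfc <- as.vector(fit$coefficients %*% cvec)
  u <- sqrt(drop(t(cvec) %*% fit$cov_unscaled %*% cvec))
  d <- fit$df_residual
  d0 <- params$d0
  if (d0 == 0) {
    s2_post <- fit$sigma2
    df_total <- d
  } else if (is.infinite(d0)) {
    s2_post <- rep(params$s0sq, length(lfc))
    df_total <- Inf
  } else {
    s2_post <- (d0 * params$s0sq + d * fit$sigma2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- lfc / (u * sqrt(s2_post))
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  adj <- stats::p.adjust(p, method = if (adjust == "BH") "BH" else
    if (adjust == "holm") "holm" else "none")
  out <- data.frame(
    probe_id = fit$probes$probe_id,
    gene_id = fit$probes$gene_id,
    logFC = lfc, t = tstat, p_value = p, adj_p_value = adj,
    significant = adj < alpha,
    direction = ifelse(lfc > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contrast_table", "data.frame")
  attr(out, "contrast") <- cname
  attr(out, "alpha") <- alpha
  out
}

#' Full differential-expression stage
#'
#' Convenience wrapper: consensus block correlation, GLS fit, moderation,
#' and one [contrast_tests] table per contrast in the design.
#'
#' @param x a normalized [expression_experiment].
#' @param design a [design_spec] with contrasts.
#' @param adjust,alpha passed to [contrast_tests].
#' @param rho intra-block correlation; estimated when `NULL`.
#' @param trim consensus trimming fraction.
#' @return list with `tables` (named list of contrast tables), `fit`,
#'   `params`, `rho`.
#' @export
run_de <- function(x, design, adjust = "BH", alpha = 0.05, rho = NULL,
                   trim = 0.15) {
  if (is.null(rho))
    rho <- as.numeric(estimate_consensus_correlation(x, design, trim = trim))
  fit <- fit_gls(x, design, rho = rho)
  params <- moderate(fit)
  tables <- lapply(names(design$contrasts), function(cn)
    contrast_tests(fit, params, cn, adjust = adjust, alpha = alpha))
  names(tables) <- names(design$contrasts)
  list(tables = tables, fit = fit, params = params, rho = rho)
}
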