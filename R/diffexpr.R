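# Per-gene linear modelling of log2-CPM with empirical-Bayes variance
# moderation and contrast testing on the 2x2 factorial design.
#
# The default parameterization is one coefficient per (x_A, x_B) cell
# ("cell means"): ctrl, A, B, AB. Contrasts are weight vectors over those
# coefficients, e.g. AB_vs_A = c(0, -1, 0, 1).

#' Filter lowly expressed genes
#'
#' Keeps genes with counts-per-million at or above `min_cpm` in at least
#' `min_samples` samples; gene order is preserved.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting the threshold
#'   (default 3, roughly the smallest condition size).
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_cpm = 1, min_samples = 3L) {
  counts <- validate_counts(counts)
  stopifnot(min_cpm >= 0, min_samples >= 0)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) stop("all genes removed by the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million
#'
#' Computes `log2((count + prior_count) / (libsize + 2 * prior_count) * 1e6)`.
#' Library-size normalization only; no between-sample scaling factors are
#' applied, so users wanting TMM-style normalization should pre-scale.
#'
#' @param counts integer matrix, genes x samples.
#' @param prior_count positive offset avoiding log of zero (default 0.5).
#' @return numeric matrix of log2-CPM values, same dimnames.
#' @export
log_cpm <- function(counts, prior_count = 0.5) {
  counts <- validate_counts(counts)
  stop_if_not_scalar_pos(prior_count, "prior_count")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  t(log2(t(counts + prior_count) / (lib + 2 * prior_count) * 1e6))
}

# shared count-matrix validation
validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0) || any(!is.finite(counts))) stop("counts must be non-negative and finite")
  counts
}

#' Validate a factorial design table
#'
#' @param design data.frame with columns `sample`, `x_A`, `x_B` and
#'   optionally `time`, `replicate`.
#' @param sample_ids sample ids the design must match exactly (order ignored).
#' @return the design, reordered to `sample_ids`.
#' @export
validate_design <- function(design, sample_ids = NULL) {
  need <- c("sample", "x_A", "x_B")
  if (!all(need %in% names(design)))
    stop("design must have columns sample, x_A, x_B")
  bad <- which(!(design$x_A %in% c(0, 1)) | !(design$x_B %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("design row %d: x_A and x_B must be 0 or 1", bad[1]))
  if (anyDuplicated(design$sample)) stop("duplicate sample ids in design")
  if (!is.null(sample_ids)) {
    if (!setequal(design$sample, sample_ids))
      stop("design sample ids do not match the count matrix")
    design <- design[match(sample_ids, design$sample), , drop = FALSE]
  }
  design
}

# Cell-means design matrix over the four (x_A, x_B) cells present.
.design_matrix <- function(design) {
  cell <- factor(paste0(design$x_A, design$x_B),
                 levels = c("00", "10", "01", "11"),
                 labels = c("ctrl", "A", "B", "AB"))
  cell <- droplevels(cell)
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  rownames(X) <- design$sample
  X
}

#' Fit per-gene linear models
#'
#' Ordinary least squares of each gene's log-expression on the cell-means
#' design (one coefficient per treatment cell). Returns the per-gene
#' coefficients, residual variances and degrees of freedom that feed the
#' empirical-Bayes moderation step.
#'
#' @param expr numeric matrix of log-expression, genes x samples.
#' @param design design table (see [validate_design()]).
#' @return object of class `gene_fit` with elements `coefficients`
#'   (genes x cells), `sigma2` (residual variances), `df_residual`,
#'   `cov_unscaled` (the common \eqn{(X'X)^{-1}}), `design_matrix`.
#' @export
fit_gene_models <- function(expr, design) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  design <- validate_design(design, colnames(expr))
  X <- .design_matrix(design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design is rank deficient")
  df <- nrow(X) - qx$rank
  if (df <= 0) stop("no residual degrees of freedom")
  XtXinv <- chol2inv(qr.R(qx))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  B <- t(qr.coef(qx, t(expr)))              # genes x cells
  colnames(B) <- colnames(X)
  res <- expr - B %*% t(X)
  s2 <- rowSums(res^2) / df
  structure(list(coefficients = B, sigma2 = s2, df_residual = df,
                 cov_unscaled = XtXinv, design_matrix = X),
            class = "gene_fit")
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment matching on the log residual variances: under the hierarchical
#' model the log sample variances are shifted log-F, so their mean and
#' variance determine (d0, s0^2) through digamma/trigamma identities; the
#' trigamma equation is inverted by Newton iteration. Posterior variances
#' are the degree-of-freedom-weighted average
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}.
#'
#' When the observed log-variance spread is no larger than expected from
#' sampling alone the prior df is infinite and all variances shrink to the
#' common value; when every gene has zero residual variance the same limit
#' is returned with a warning.
#'
#' @param fit a `gene_fit` object.
#' @return object of class `ebayes_fit` with `d0`, `s0_2`, `s2_post`, and
#'   the originating fit.
#' @export
ebayes_moderate <- function(fit) {
  stopifnot(inherits(fit, "gene_fit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  ok <- s2 > 0
  if (!any(ok)) {
    warning("all residual variances are zero; prior df set infinite")
    return(structure(list(d0 = Inf, s0_2 = 0,
                          s2_post = rep(0, length(s2)), fit = fit),
                     class = "ebayes_fit"))
  }
  if (sum(ok) < 10L)
    warning("fewer than 10 genes with positive variance; hyperparameter estimates are unstable")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- .posterior_var(s2, d, d0, s0_2)
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, fit = fit),
            class = "ebayes_fit")
}

.posterior_var <- function(s2, d, d0, s0_2) {
  if (is.infinite(d0)) rep(s0_2, length(s2))
  else if (d0 == 0) s2
  else (d0 * s0_2 + d * s2) / (d0 + d)
}

#' Moderated-t contrast test
#'
#' Tests a linear contrast of the cell-mean coefficients for every gene:
#' logFC = c'beta, moderated t = logFC / (u_c * s_post), two-sided p from a
#' t-distribution on d0 + d_g degrees of freedom, Benjamini-Hochberg
#' adjusted. Setting `d0 = 0` (via `moderate = FALSE` in callers, or an
#' `ebayes_fit` built with d0 forced to 0) reproduces the ordinary per-gene
#' OLS t-test.
#'
#' @param eb an `ebayes_fit` object (use [no_moderation()] for plain OLS
#'   tests).
#' @param contrast numeric weight vector over the fitted coefficients, or a
#'   name from [standard_contrasts()].
#' @param name label stored in the result (defaults to a deparse of the
#'   contrast).
#' @return data.frame of class `de_table`: gene, logFC, t, p, adj_p,
#'   with attributes `contrast` and `df_total`.
#' @export
contrast_test <- function(eb, contrast, name = NULL) {
  stopifnot(inherits(eb, "ebayes_fit"))
  fit <- eb$fit
  cells <- colnames(fit$coefficients)
  if (is.character(contrast) && length(contrast) == 1L) {
    name <- name %||% contrast
    contrast <- standard_contrasts(cells)[[contrast]]
    if (is.null(contrast)) stop("unknown contrast name")
  }
  if (length(contrast) != ncol(fit$coefficients))
    stop("contrast length must equal the number of coefficients")
  name <- name %||% paste(deparse(contrast), collapse = "")
  lfc <- drop(fit$coefficients %*% contrast)
  u2 <- drop(t(contrast) %*% fit$cov_unscaled %*% contrast)
  if (all(contrast == 0)) {
    tstat <- rep(0, length(lfc))
    p <- rep(1, length(lfc))
  } else {
    if (u2 <= 0) stop("contrast has zero unscaled variance")
    se <- sqrt(u2 * eb$s2_post)
    tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    dft <- eb$d0 + fit$df_residual
    p <- 2 * stats::pt(-abs(tstat), df = dft)
  }
  out <- data.frame(gene = rownames(fit$coefficients), logFC = lfc,
                    t = tstat, p = p, adj_p = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- name
  attr(out, "df_total") <- eb$d0 + fit$df_residual
  class(out) <- c("de_table", "data.frame")
  out
}

#' Named contrasts for the 2x2 factorial cell-means fit
#'
#' @param cells coefficient names, a subset of `c("ctrl","A","B","AB")`.
#' @return named list of weight vectors: the three treatment-vs-control
#'   comparisons, the two combination-vs-monotherapy comparisons, and the
#'   interaction `(AB - A) - (B - ctrl)`.
#' @export
standard_contrasts <- function(cells = c("ctrl", "A", "B", "AB")) {
  w <- function(...) {
    v <- stats::setNames(rep(0, length(cells)), cells)
    upd <- c(...)
    v[names(upd)] <- upd
    v
  }
  list(
    A_vs_ctrl  = w(A = 1, ctrl = -1),
    B_vs_ctrl  = w(B = 1, ctrl = -1),
    AB_vs_ctrl = w(AB = 1, ctrl = -1),
    AB_vs_A    = w(AB = 1, A = -1),
    AB_vs_B    = w(AB = 1, B = -1),
    interaction = w(AB = 1, A = -1, B = -1, ctrl = 1)
  )
}

#' Unmoderated (ordinary least squares) variant of a fit
#'
#' Wraps a `gene_fit` with d0 = 0 so that [contrast_test()] reproduces the
#' plain per-gene pooled-variance t-test (as used for e.g. ANOVA-style
#' per-transcript screens with unadjusted p).
#'
#' @param fit a `gene_fit` object.
#' @return an `ebayes_fit` with d0 = 0 and posterior variances equal to the
#'   per-gene sample variances.
#' @export
no_moderation <- function(fit) {
  stopifnot(inherits(fit, "gene_fit"))
  structure(list(d0 = 0, s0_2 = NA_real_, s2_post = fit$sigma2, fit = fit),
            class = "ebayes_fit")
}

#' Run the four-condition differential-expression pipeline
#'
#' Convenience wrapper: filter, log-CPM, fit, moderate, and test the named
#' contrasts. Returns one `de_table` per contrast, all computed on the same
#' post-filter gene universe.
#'
#' @param counts genes x samples count matrix.
#' @param design factorial design table.
#' @param contrasts character vector of contrast names
#'   (see [standard_contrasts()]).
#' @param min_cpm,min_samples low-count filter (see [filter_low_counts()]).
#' @param prior_count log-CPM offset.
#' @param moderate use empirical-Bayes moderation (default TRUE).
#' @return named list of `de_table` data.frames plus attributes `ebayes`
#'   and `universe`.
#' @export
run_de <- function(counts, design,
                   contrasts = c("A_vs_ctrl", "B_vs_ctrl", "AB_vs_ctrl",
                                 "AB_vs_A", "AB_vs_B"),
                   min_cpm = 1, min_samples = 3L, prior_count = 0.5,
                   moderate = TRUE) {
  kept <- filter_low_counts(counts, min_cpm, min_samples)
  expr <- log_cpm(kept, prior_count)
  fit <- fit_gene_models(expr, design)
  eb <- if (moderate) ebayes_moderate(fit) else no_moderation(fit)
  out <- lapply(contrasts, function(cn) contrast_test(eb, cn))
  names(out) <- contrasts
  attr(out, "ebayes") <- eb
  attr(out, "universe") <- rownames(kept)
  out
}
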