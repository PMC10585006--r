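# Rank-based single-sample gene-set scoring, tertile stratification, and
# preranked gene-set enrichment.

#' Rank-based single-sample gene-set score
#'
#' For each sample, genes are ranked ascending by expression (average ranks
#' for ties); the score is the centered, normalized mean rank of the set
#' genes: with n_G set genes among N total, mean set rank Rbar, minimum
#' attainable mean rank (n_G + 1)/2 and maximum N - (n_G - 1)/2, the score
#' is `(Rbar - Rmin) / (Rmax - Rmin) - 0.5`, so it always lies in
#' \[-0.5, 0.5\] and a high score corresponds to high expression of the set.
#' Being rank-based, it is invariant to any strictly monotone transform of
#' a sample's expression values.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param gene_set character vector of gene ids; genes absent from `expr`
#'   are dropped (at least one must be present).
#' @return data.frame with columns sample, score, n_set_genes_used.
#' @export
singscore <- function(expr, gene_set) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
  set <- intersect(unique(gene_set), rownames(expr))
  if (length(set) == 0L) stop("no gene-set genes present in the matrix")
  N <- nrow(expr)
  nG <- length(set)
  rmin <- (nG + 1) / 2
  rmax <- N - (nG - 1) / 2
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    rbar <- mean(r[set])
    if (rmax == rmin) return(0)   # set is the whole universe
    (rbar - rmin) / (rmax - rmin) - 0.5
  }, numeric(1))
  data.frame(sample = colnames(expr), score = scores,
             n_set_genes_used = nG, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign samples to score tertiles
#'
#' Samples are sorted ascending by score (ties broken by sample id for
#' determinism); the bottom tertile is the first ceiling(n/3) samples, the
#' top tertile the last floor(n/3), the remainder the middle. With n = 62
#' this gives the 21/21/20 split.
#'
#' @param scores data.frame with columns `sample` and `score`.
#' @return data.frame with columns sample, score, tertile
#'   (factor bottom/middle/top), ordered by ascending score.
#' @export
assign_tertiles <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("sample", "score") %in% names(scores)))
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 scored samples")
  o <- order(scores$score, scores$sample)
  out <- scores[o, c("sample", "score"), drop = FALSE]
  n_bottom <- ceiling(n / 3)
  n_top <- floor(n / 3)
  tert <- rep("middle", n)
  tert[seq_len(n_bottom)] <- "bottom"
  tert[seq.int(n - n_top + 1L, n)] <- "top"
  out$tertile <- factor(tert, levels = c("bottom", "middle", "top"))
  rownames(out) <- NULL
  out
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov-style running sum over a ranked gene list:
#' walking the list from top to bottom, set genes increment the sum in
#' proportion to |metric|^weight (normalized to 1 over the set) and
#' non-set genes decrement it by 1/(N - n_G); the enrichment score ES is
#' the extremum of the running sum. The null is built by gene-set
#' permutation: `n_perm` random sets of the same size; NES is ES divided by
#' the mean |ES*| of same-sign permutations, and the p-value is the
#' one-sided permutation tail probability.
#'
#' @param metric named numeric vector: the ranking statistic per gene
#'   (e.g. a moderated t); genes are ranked by decreasing metric.
#' @param gene_set character vector of gene ids.
#' @param weight exponent on |metric| for hit increments (default 1; 0
#'   gives the unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of gene-set permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return list with `ES`, `NES`, `p`, `n_perm`, `seed`, `running` (the
#'   running-sum vector in ranked order), `n_set_used`.
#' @export
preranked_gsea <- function(metric, gene_set, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  stopifnot(!is.null(names(metric)), n_perm >= 100L)
  o <- order(metric, decreasing = TRUE)
  metric <- metric[o]
  hits <- names(metric) %in% gene_set
  if (!any(hits)) stop("gene set has no genes in the ranked list")
  es <- .gsea_es(metric, hits, weight, keep_running = TRUE)
  nG <- sum(hits)
  perm_es <- local_seed(seed, stream = 11L, {
    vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(metric))
      ph[sample.int(length(metric), nG)] <- TRUE
      .gsea_es(metric, ph, weight)$ES
    }, numeric(1))
  })
  same <- perm_es[sign(perm_es) == sign(es$ES)]
  if (length(same) == 0L) {
    nes <- sign(es$ES) * Inf
    p <- 1 / (n_perm + 1)
  } else {
    nes <- es$ES / mean(abs(same))
    p <- (sum(abs(same) >= abs(es$ES)) + 1) / (length(same) + 1)
  }
  list(ES = es$ES, NES = nes, p = p, n_perm = n_perm, seed = seed,
       running = es$running, n_set_used = nG)
}

.gsea_es <- function(metric, hits, weight, keep_running = FALSE) {
  N <- length(metric)
  nG <- sum(hits)
  w <- abs(metric)^weight
  inc <- numeric(N)
  denom <- sum(w[hits])
  if (denom == 0) {                 # all set metrics zero: fall back to KS
    inc[hits] <- 1 / nG
  } else inc[hits] <- w[hits] / denom
  inc[!hits] <- -1 / (N - nG)
  running <- cumsum(inc)
  i <- which.max(abs(running))
  list(ES = running[i], running = if (keep_running) running else NULL)
}
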