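# Extraction of the combination-only gene signature by three overlap
# analyses, and quantification of super-additive (synergistic) expression
# changes against the additive expectation (the sum of the two monotherapy
# log fold-changes).

#' Differentially expressed gene set at a significance threshold
#'
#' @param de a `de_table` (see [contrast_test()]).
#' @param alpha adjusted-p threshold, in (0, 1).
#' @return object of class `deg_set`: list with `genes`, `alpha`,
#'   `contrast`, `universe`.
#' @export
deg_set <- function(de, alpha = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "adj_p") %in% names(de)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(genes = de$gene[de$adj_p < alpha], alpha = alpha,
                 contrast = attr(de, "contrast") %||% NA_character_,
                 universe = de$gene),
            class = "deg_set")
}

#' Extract the combination-specific signature by three overlap analyses
#'
#' list 1 is the combination-vs-monotherapy-A DEGs with the
#' B-vs-control DEGs removed; list 2 is the combination-vs-monotherapy-B
#' DEGs with the A-vs-control DEGs removed; the signature is their
#' intersection: genes that respond to the combination but to neither
#' monotherapy.
#'
#' All four DEG sets must come from the same post-filter gene universe and
#' the same alpha; mismatches are an error rather than being silently
#' intersected.
#'
#' @param deg_AB_vs_A,deg_B_vs_ctrl,deg_AB_vs_B,deg_A_vs_ctrl `deg_set`
#'   objects for the four contrasts.
#' @return object of class `combination_signature`: list with `list1`,
#'   `list2`, `signature` (character vectors) and `counts` of every
#'   intermediate set.
#' @export
extract_combination_signature <- function(deg_AB_vs_A, deg_B_vs_ctrl,
                                          deg_AB_vs_B, deg_A_vs_ctrl) {
  sets <- list(deg_AB_vs_A, deg_B_vs_ctrl, deg_AB_vs_B, deg_A_vs_ctrl)
  stopifnot(all(vapply(sets, inherits, logical(1), "deg_set")))
  alphas <- vapply(sets, `[[`, numeric(1), "alpha")
  if (length(unique(alphas)) != 1L)
    stop("all DEG sets must use the same alpha")
  for (s in sets[-1])
    if (!identical(sort(s$universe), sort(sets[[1]]$universe)))
      stop("DEG sets computed on different gene universes")
  list1 <- setdiff(deg_AB_vs_A$genes, deg_B_vs_ctrl$genes)
  list2 <- setdiff(deg_AB_vs_B$genes, deg_A_vs_ctrl$genes)
  sig <- intersect(list1, list2)
  if (length(sig) == 0L) warning("empty combination signature")
  structure(list(
    list1 = list1, list2 = list2, signature = sig,
    counts = c(deg_AB_vs_A = length(deg_AB_vs_A$genes),
               deg_B_vs_ctrl = length(deg_B_vs_ctrl$genes),
               deg_AB_vs_B = length(deg_AB_vs_B$genes),
               deg_A_vs_ctrl = length(deg_A_vs_ctrl$genes),
               list1 = length(list1), list2 = length(list2),
               signature = length(sig)),
    alpha = alphas[1]), class = "combination_signature")
}

#' Split a signature by direction of the combination effect
#'
#' Direction is taken from the combination-vs-control log fold-change:
#' negative logFC genes are "down", positive are "up"; exact zeros are
#' reported separately.
#'
#' @param sig a `combination_signature`.
#' @param de_AB_vs_ctrl `de_table` for the combination-vs-control contrast.
#' @return list with character vectors `up`, `down`, `zero`.
#' @export
split_by_direction <- function(sig, de_AB_vs_ctrl) {
  stopifnot(inherits(sig, "combination_signature"))
  idx <- match(sig$signature, de_AB_vs_ctrl$gene)
  if (anyNA(idx)) stop("signature gene missing from the DE table")
  lfc <- de_AB_vs_ctrl$logFC[idx]
  list(up = sig$signature[lfc > 0],
       down = sig$signature[lfc < 0],
       zero = sig$signature[lfc == 0])
}

#' Threshold-derived gene set (significance + fold-change rule)
#'
#' Selects genes with adjusted p below `p_thr` passing a directional logFC
#' cut, as used to derive an expression signature from a case-vs-normal
#' comparison (e.g. logFC > 1.5 for an "up in disease" set).
#'
#' @param de a `de_table`.
#' @param p_thr adjusted-p threshold (default 0.05).
#' @param lfc_thr positive logFC magnitude threshold (default 1.5).
#' @param direction `"up"` (logFC > lfc_thr), `"down"` (logFC < -lfc_thr),
#'   or `"both"`.
#' @return character vector of gene ids.
#' @export
threshold_signature <- function(de, p_thr = 0.05, lfc_thr = 1.5,
                                direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(p_thr > 0, lfc_thr >= 0)
  pass_p <- de$adj_p < p_thr
  pass_lfc <- switch(direction,
    up = de$logFC > lfc_thr,
    down = de$logFC < -lfc_thr,
    both = abs(de$logFC) > lfc_thr)
  de$gene[pass_p & pass_lfc]
}

#' Build the per-gene synergy table against the additive expectation
#'
#' For each gene the additive expectation is the sum of the two monotherapy
#' log fold-changes (`lfc_add = lfc_A + lfc_B`) and the excess is the
#' observed combination effect minus that expectation. A gene is flagged
#' synergistic when the combination effect exceeds the additive expectation
#' in its own direction: for a downregulated gene (lfc_AB < 0) when
#' `lfc_AB < lfc_add`, for an upregulated gene when `lfc_AB > lfc_add`;
#' genes with lfc_AB exactly 0 are never flagged.
#'
#' @param de_A_vs_ctrl,de_B_vs_ctrl,de_AB_vs_ctrl `de_table`s for the three
#'   treatment-vs-control contrasts.
#' @param genes gene ids to tabulate (all must be present in all three
#'   tables); default the full shared table.
#' @return data.frame of class `synergy_table`: gene, lfc_A, lfc_B, lfc_AB,
#'   lfc_add, excess, synergy.
#' @export
build_synergy_table <- function(de_A_vs_ctrl, de_B_vs_ctrl, de_AB_vs_ctrl,
                                genes = NULL) {
  genes <- genes %||% de_AB_vs_ctrl$gene
  pick <- function(de) {
    idx <- match(genes, de$gene)
    if (anyNA(idx)) stop("gene missing from a DE table: ",
                         genes[which(is.na(idx))[1]])
    de$logFC[idx]
  }
  lfc_A <- pick(de_A_vs_ctrl)
  lfc_B <- pick(de_B_vs_ctrl)
  lfc_AB <- pick(de_AB_vs_ctrl)
  lfc_add <- lfc_A + lfc_B
  synergy <- (lfc_AB < 0 & lfc_AB < lfc_add) |
             (lfc_AB > 0 & lfc_AB > lfc_add)
  out <- data.frame(gene = genes, lfc_A = lfc_A, lfc_B = lfc_B,
                    lfc_AB = lfc_AB, lfc_add = lfc_add,
                    excess = lfc_AB - lfc_add, synergy = synergy,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("synergy_table", "data.frame")
  out
}

#' Group test of combination effects against the additive expectation
#'
#' Kruskal-Wallis test across the four per-gene value groups (monotherapy A,
#' monotherapy B, observed combination, additive expectation) followed by
#' Dunn's post-test of the observed-combination group against the additive
#' expectation, plus the fraction of genes flagged synergistic.
#'
#' @param tab a `synergy_table` with at least 5 genes.
#' @return list with `kruskal` (H, df, p), `dunn_AB_vs_add` (z, p, adj_p),
#'   `fraction_synergistic`, `n_genes`.
#' @export
synergy_test <- function(tab) {
  stopifnot(inherits(tab, "synergy_table"))
  if (nrow(tab) < 5L) stop("need at least 5 genes")
  groups <- list(lfc_A = tab$lfc_A, lfc_B = tab$lfc_B,
                 lfc_AB = tab$lfc_AB, lfc_add = tab$lfc_add)
  kw <- kruskal_wallis(groups)
  dunn <- dunn_posttest(groups,
                        comparisons = list(c("lfc_AB", "lfc_add")))
  list(kruskal = kw, dunn_AB_vs_add = dunn,
       fraction_synergistic = mean(tab$synergy), n_genes = nrow(tab))
}
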