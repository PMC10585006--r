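mk_deg <- function(genes, universe, contrast = "c", alpha = 0.05) {
  structure(list(genes = genes, alpha = alpha, contrast = contrast,
                 universe = universe), class = "deg_set")
}

mk_de <- function(genes, lfc, adj_p = rep(0.01, length(genes))) {
  out <- data.frame(gene = genes, logFC = lfc, t = lfc * 2,
                    p = adj_p / 2, adj_p = adj_p,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

test_that("three-overlap extraction follows its set algebra", {
  uni <- paste0("g", 1:10)
  sig <- extract_combination_signature(
    mk_deg(c("g1", "g2", "g3"), uni), mk_deg("g3", uni),
    mk_deg(c("g1", "g2", "g4"), uni), mk_deg("g4", uni))
  expect_setequal(sig$list1, c("g1", "g2"))
  expect_setequal(sig$list2, c("g1", "g2"))
  expect_setequal(sig$signature, c("g1", "g2"))
  expect_true(all(sig$signature %in% sig$list1))
  expect_true(all(sig$signature %in% sig$list2))

  # exclusion list covering the combination DEGs empties the signature
  expect_warning(
    sig0 <- extract_combination_signature(
      mk_deg(c("g1", "g2"), uni), mk_deg(c("g1", "g2", "g5"), uni),
      mk_deg("g1", uni), mk_deg("g9", uni)),
    "empty")
  expect_length(sig0$signature, 0)

  # mismatched universes or alphas are an error, not a silent intersection
  expect_error(extract_combination_signature(
    mk_deg("g1", uni), mk_deg("g2", uni[1:5]),
    mk_deg("g1", uni), mk_deg("g2", uni)), "universes")
  expect_error(extract_combination_signature(
    mk_deg("g1", uni), mk_deg("g2", uni, alpha = 0.01),
    mk_deg("g1", uni), mk_deg("g2", uni)), "alpha")
})

test_that("signature extraction agrees with brute-force set recomputation at several alphas", {
  fx <- sim_de_fixture(1L)
  for (alpha in c(0.01, 0.05, 0.2)) {
    sets <- lapply(fx$de[c("AB_vs_A", "B_vs_ctrl", "AB_vs_B",
                           "A_vs_ctrl")], deg_set, alpha = alpha)
    sig <- extract_combination_signature(sets$AB_vs_A, sets$B_vs_ctrl,
                                         sets$AB_vs_B, sets$A_vs_ctrl)
    pick <- function(cn) fx$de[[cn]]$gene[fx$de[[cn]]$adj_p < alpha]
    l1 <- setdiff(pick("AB_vs_A"), pick("B_vs_ctrl"))
    l2 <- setdiff(pick("AB_vs_B"), pick("A_vs_ctrl"))
    expect_setequal(sig$signature, intersect(l1, l2))
  }
})

test_that("planted combination-only genes are recovered and mislabeled classes stay out", {
  fx <- sim_de_fixture(1L)
  sig <- extract_combination_signature(fx$sets$AB_vs_A, fx$sets$B_vs_ctrl,
                                       fx$sets$AB_vs_B, fx$sets$A_vs_ctrl)
  truth <- fx$sim$truth
  combo <- truth$gene[truth$class == "combo_only"]
  mono <- truth$gene[truth$class %in% c("A_only", "B_only")]
  expect_gte(mean(combo %in% sig$signature), 0.85)
  expect_length(intersect(sig$signature, mono), 0)

  # planted interaction is negative: every recovered combo gene lands in
  # the down split
  split <- split_by_direction(sig, fx$de$AB_vs_ctrl)
  expect_true(all(intersect(combo, sig$signature) %in% split$down))
  expect_length(intersect(split$up, combo), 0)
})

test_that("direction split partitions the signature", {
  uni <- paste0("g", 1:6)
  sig <- structure(list(signature = uni, list1 = uni, list2 = uni),
                   class = "combination_signature")
  de <- mk_de(uni, c(-2, -1, 0, 1, 2, -0.5))
  sp <- split_by_direction(sig, de)
  expect_setequal(sp$down, c("g1", "g2", "g6"))
  expect_setequal(sp$up, c("g4", "g5"))
  expect_setequal(sp$zero, "g3")
  expect_length(c(sp$up, sp$down, sp$zero), length(uni))
  expect_error(split_by_direction(sig, de[-1, ]), "missing")
})

test_that("threshold signature applies the p and logFC rules", {
  de <- mk_de(paste0("g", 1:5), c(1.6, -1.8, 0.3, 2.0, 1.6),
              adj_p = c(0.01, 0.01, 0.01, 0.2, 0.04))
  expect_setequal(threshold_signature(de, 0.05, 1.5, "up"),
                  c("g1", "g5"))
  expect_setequal(threshold_signature(de, 0.05, 1.5, "down"), "g2")
  expect_setequal(threshold_signature(de, 0.05, 1.5, "both"),
                  c("g1", "g2", "g5"))
  # lfc_thr = 0 with a permissive p keeps every gene with nonzero logFC
  expect_setequal(threshold_signature(de, 1 - 1e-9, 0, "both"),
                  paste0("g", 1:5))
  expect_setequal(threshold_signature(de, 1 - 1e-9, 0, "up"),
                  paste0("g", c(1, 3, 4, 5)))

  # brute-force row filter on a random table
  withr::with_seed(13, {
    rde <- mk_de(sprintf("r%03d", 1:200), rnorm(200, sd = 2),
                 adj_p = runif(200))
  })
  got <- threshold_signature(rde, 0.1, 1.2, "down")
  manual <- rde$gene[rde$adj_p < 0.1 & rde$logFC < -1.2]
  expect_identical(got, manual)
})

test_that("synergy table applies the additive-expectation rule", {
  tabA <- mk_de(c("g1", "g2"), c(-0.5, 0.2))
  tabB <- mk_de(c("g1", "g2"), c(-0.4, 0.3))
  tabAB <- mk_de(c("g1", "g2"), c(-1.5, 0.5))
  st <- build_synergy_table(tabA, tabB, tabAB)
  expect_equal(st$lfc_add, c(-0.9, 0.5))
  expect_equal(st$excess, c(-0.6, 0))
  expect_identical(st$synergy, c(TRUE, FALSE))  # boundary gene not flagged

  # up-direction synergy
  st2 <- build_synergy_table(mk_de("u", 0.5), mk_de("u", 0.4),
                             mk_de("u", 1.5))
  expect_true(st2$synergy)
  # zero combination effect is never synergistic
  st3 <- build_synergy_table(mk_de("z", -1), mk_de("z", -1), mk_de("z", 0))
  expect_false(st3$synergy)
  expect_error(build_synergy_table(tabA, tabB, tabAB, genes = "gX"),
               "missing")
})

test_that("synergy group test behaves at its degenerate limits", {
  n <- 10
  lfc <- rnorm(n)
  tab <- build_synergy_table(mk_de(paste0("g", 1:n), lfc / 2),
                             mk_de(paste0("g", 1:n), lfc / 2),
                             mk_de(paste0("g", 1:n), lfc))
  # observed combination equals the additive expectation exactly
  expect_equal(mean(tab$synergy), 0)
  rep <- synergy_test(tab)
  expect_gt(rep$dunn_AB_vs_add$p, 0.9)

  # all four value groups identical constants (only possible at zero,
  # since lfc_add = lfc_A + lfc_B): rank test finds nothing
  const <- build_synergy_table(mk_de(paste0("g", 1:5), rep(0, 5)),
                               mk_de(paste0("g", 1:5), rep(0, 5)),
                               mk_de(paste0("g", 1:5), rep(0, 5)))
  expect_equal(synergy_test(const)$kruskal$H, 0)
  expect_equal(synergy_test(const)$kruskal$p, 1)
  expect_error(synergy_test(tab[1:3, ]), "at least 5")
})

test_that("planted super-additive genes are flagged and additive genes are not", {
  fx <- sim_de_fixture(1L)
  truth <- fx$sim$truth
  combo <- intersect(truth$gene[truth$class == "combo_only"],
                     attr(fx$de, "universe"))
  tab <- build_synergy_table(fx$de$A_vs_ctrl, fx$de$B_vs_ctrl,
                             fx$de$AB_vs_ctrl, genes = combo)
  expect_gt(synergy_test(tab)$fraction_synergistic, 0.9)

  additive <- intersect(truth$gene[truth$class == "additive"],
                        attr(fx$de, "universe"))
  tab_add <- build_synergy_table(fx$de$A_vs_ctrl, fx$de$B_vs_ctrl,
                                 fx$de$AB_vs_ctrl, genes = additive)
  # no interaction planted: the excess is centered on zero
  expect_lt(abs(mean(tab_add$excess)), 0.1)
})
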