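# synergysig

Deriving **combination-specific gene signatures** from 2x2 factorial
RNA-seq designs, quantifying **super-additive (synergistic) expression
changes**, carrying the signature into **patient survival stratification**,
and quantifying **DNA-replication dynamics** from single-molecule DNA-fiber
assays — with a synthetic-data module that plants ground truth for every
analysis, so the whole pipeline is testable offline.

The motivating setting is combination therapy in diffuse large B cell
lymphoma (a microRNA mimic, "treatment A", combined with a BTK inhibitor,
"treatment B"), where the combination represses a DNA-replication / cell
cycle program that neither monotherapy touches, and where high
pre-treatment expression of that program marks poor-survival patients.
The package is agnostic to what A and B actually are.

## What it computes

**Moderated-t differential expression.** Per-gene OLS on log2-CPM over the
four treatment cells (ctrl, A, B, AB), with empirical-Bayes variance
moderation: hyperparameters (d0, s0²) estimated by moment matching on
log s² via digamma/trigamma inversion, posterior variances
s̃² = (d0·s0² + d·s²)/(d0 + d), contrasts tested on d0 + d df,
Benjamini-Hochberg adjusted.

**The three-overlap signature.** With DEG sets at adjusted p < α on one
shared gene universe:

    list1     = DEG(AB vs A)  \  DEG(B vs ctrl)
    list2     = DEG(AB vs B)  \  DEG(A vs ctrl)
    signature = list1 ∩ list2

split by the sign of the AB-vs-control logFC. Genes in the signature
responded to the combination but to neither monotherapy.

**Synergy against the additive expectation.** Per gene,
lfc_add = lfc_A + lfc_B; a gene is synergistic when the combination effect
exceeds that expectation in its own direction (down gene:
lfc_AB < lfc_add; up gene: lfc_AB > lfc_add). Group-level testing by
Kruskal-Wallis + Dunn's post-test of AB versus the additive expectation.

**Scoring and survival.** Rank-based single-sample scores
(centered normalized mean rank of set genes, in [-0.5, 0.5]), tertile
stratification (62 patients split 21/21/20), Kaplan-Meier curves and the
log-rank test between extreme tertiles, plus preranked gene-set enrichment
with a gene-set-permutation null.

**Fiber dynamics.** Classification of dual-pulse track patterns
(red-green = ongoing fork, green-red-green = first-label origin, ...),
fork rate = green track length x 2.59 kb/µm / 20 min, origin firing = %
of first-label origins among red-containing structures, and
condition-level comparisons (Kruskal-Wallis + Dunn for pooled fork rates,
one-way ANOVA for per-replicate origin percentages).

**Shared primitives**, implemented from their formulas and cross-checked
against independent oracles in the test suite: BH step-up adjustment,
tie-corrected Kruskal-Wallis, Dunn's post-test, iterative two-sided Grubbs
outlier removal, one-way ANOVA, correlation; tumor caliper arithmetic
(volume = width² x length / 2, baseline-normalized growth).

## Worked example

Simulate the default study conditions (2000 genes, 3 replicates per cell,
50 genes each of A-only / B-only / additive / combination-only classes at
2 log2-unit effects), run the DE + signature pipeline, and stratify a
simulated 62-patient cohort by the recovered signature:

```r
library(synergysig)

sim <- gen_factorial_counts(factorial_sim_config(seed = 1))
de  <- run_de(sim$counts, sim$design)
sets <- lapply(de[c("AB_vs_A", "B_vs_ctrl", "AB_vs_B", "A_vs_ctrl")],
               deg_set, alpha = 0.05)
sig <- extract_combination_signature(sets$AB_vs_A, sets$B_vs_ctrl,
                                     sets$AB_vs_B, sets$A_vs_ctrl)
sig$counts
#>   deg_AB_vs_A deg_B_vs_ctrl   deg_AB_vs_B deg_A_vs_ctrl         list1
#>           131            84           127            76            59
#>         list2     signature
#>            57            47

parts <- split_by_direction(sig, de$AB_vs_ctrl)
length(parts$down); length(parts$up)
#> [1] 47
#> [1] 0

tab <- build_synergy_table(de$A_vs_ctrl, de$B_vs_ctrl, de$AB_vs_ctrl,
                           genes = parts$down)
rep <- synergy_test(tab)
#> Kruskal-Wallis H = 96.7 (p = 7.94e-21); AB vs additive Dunn p = 1.29e-15
#> fraction synergistic = 1.00

co <- gen_patient_cohort(cohort_sim_config(n_patients = 62, seed = 42),
                         rownames(sim$counts), parts$down)
strat <- stratify_and_compare(co$expr, parts$down, co$survival)
#> tertiles: 21 bottom / 21 middle / 20 top
#> log-rank top vs bottom: chisq = 11.19, p = 0.0008
```

Reading: the three-overlap procedure finds 47 genes (all downregulated, as
planted — the interaction effects were simulated negative), their combined
repression far exceeds the sum of the monotherapy effects (every signature
gene flagged synergistic; Dunn p ≈ 1e-15), and patients with high
signature expression have significantly worse simulated survival
(log-rank p = 0.0008), recovering the planted hazard direction.

A thin command-line wrapper over the same functions ships in
`inst/scripts/synergysig.R` (subcommands `simulate`, `de`, `signature`,
`score`, `fibers`, `growth`, `stats`).

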