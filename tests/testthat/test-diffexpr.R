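make_counts <- function(n_genes = 100L, n_samples = 8L, seed = 21L) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 10),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

make_design <- function(n_reps = 2L) {
  cells <- expand.grid(x_A = 0:1, x_B = 0:1)
  d <- cells[rep(1:4, each = n_reps), ]
  d$replicate <- rep(seq_len(n_reps), 4)
  d$sample <- sprintf("s%02d", seq_len(nrow(d)))
  d$time <- 20
  d[, c("sample", "x_A", "x_B", "time", "replicate")]
}

test_that("low-count filter applies exactly its CPM rule", {
  m <- make_counts()
  expect_identical(filter_low_counts(m, min_cpm = 0), m)

  # brute-force recomputation of the retained set
  kept <- filter_low_counts(m, min_cpm = 1000, min_samples = 3)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  manual <- rownames(m)[rowSums(cpm >= 1000) >= 3]
  expect_identical(rownames(kept), manual)

  z <- rbind(m, zero = 0L)
  expect_false("zero" %in%
                 rownames(filter_low_counts(z, min_cpm = 1,
                                            min_samples = 1)))
  expect_error(filter_low_counts(m, min_cpm = 1e9), "all genes removed")
})

test_that("log-CPM matches its closed form", {
  m <- matrix(c(0, 10, 100, 5), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m[1, 1] <- 0
  # single-cell closed form: count 0, libsize 1e6, prior 0.5
  one <- matrix(c(0, 1e6, 50, 50), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  v <- log_cpm(one, prior_count = 0.5)["a", "s1"]
  expect_equal(v, log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(v, -1.0000014, tolerance = 1e-6)

  # spreadsheet-style recomputation on a random 5x4 matrix
  withr::with_seed(9, r <- matrix(rpois(20, 40), 5, 4,
                                  dimnames = list(paste0("g", 1:5),
                                                  paste0("s", 1:4))))
  lc <- log_cpm(r, prior_count = 0.5)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(lc[i, j],
                 log2((r[i, j] + 0.5) / (sum(r[, j]) + 1) * 1e6),
                 tolerance = 1e-12)
  }
  # scale property: doubling counts and libsizes changes values only
  # through the prior-count term
  expect_equal(log_cpm(2 * r), lc, tolerance = 2 * 0.5 / min(colSums(r)))
})

test_that("per-gene OLS recovers cell means and matches lm()", {
  d <- make_design()
  # gene with identical values within every cell: zero residual variance
  y <- rep(c(1, 3, 5, 9), each = 2)
  expr <- rbind(flat = y, noisy = y + c(0.1, -0.1))
  colnames(expr) <- d$sample
  fit <- fit_gene_models(expr, d)
  expect_equal(fit$sigma2[["flat"]], 0)
  expect_equal(unname(fit$coefficients["flat", ]), c(1, 3, 5, 9))
  expect_equal(fit$df_residual, 4L)

  # single-gene fit equals lm() on the 4-condition, 2-replicate vector
  cell <- factor(paste0(d$x_A, d$x_B), levels = c("00", "10", "01", "11"))
  ref <- lm(expr["noisy", ] ~ 0 + cell)
  expect_equal(unname(fit$coefficients["noisy", ]),
               unname(coef(ref)), tolerance = 1e-12)
  expect_equal(fit$sigma2[["noisy"]],
               sum(residuals(ref)^2) / ref$df.residual, tolerance = 1e-12)
})

test_that("fits are invariant to joint sample/design permutation", {
  d <- make_design()
  expr <- matrix(rnorm(80), 10, 8,
                 dimnames = list(paste0("g", 1:10), d$sample))
  fit1 <- fit_gene_models(expr, d)
  perm <- sample(8)
  fit2 <- fit_gene_models(expr[, perm], d[perm, ])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-12)
})

test_that("empirical-Bayes shrinkage obeys its bounds and limits", {
  d <- make_design(3L)
  withr::with_seed(31, expr <- matrix(rnorm(500 * 12, sd = 1), 500, 12,
                 dimnames = list(sprintf("g%03d", 1:500), d$sample)))
  fit <- fit_gene_models(expr, d)
  eb <- ebayes_moderate(fit)
  # posterior variance lies weakly between s_g^2 and s0^2
  lo <- pmin(fit$sigma2, eb$s0_2)
  hi <- pmax(fit$sigma2, eb$s0_2)
  expect_true(all(eb$s2_post >= lo - 1e-12 & eb$s2_post <= hi + 1e-12))
  # monotone in s_g^2
  o <- order(fit$sigma2)
  expect_true(all(diff(eb$s2_post[o]) >= -1e-12))
  # homoscedastic data: strong shrinkage toward the common value
  expect_gt(eb$d0, 20)
  expect_lt(max(abs(eb$s2_post - eb$s0_2)) / eb$s0_2, 0.5)

  # d0 = 0: no moderation at all
  raw <- no_moderation(fit)
  expect_identical(raw$s2_post, fit$sigma2)
})

test_that("hyperparameter recovery from scaled inverse-chi-square variances", {
  d0_true <- 4; s02_true <- 2; d <- 8
  withr::with_seed(101, {
    sigma2 <- d0_true * s02_true / rchisq(500, d0_true)
    s2 <- sigma2 * rchisq(500, d) / d
  })
  fit <- structure(list(sigma2 = s2, df_residual = d), class = "gene_fit")
  eb <- ebayes_moderate(fit)
  expect_lt(abs(eb$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(eb$s0_2 - s02_true) / s02_true, 0.10)
})

test_that("moderated contrast tests match independent recomputation", {
  d <- make_design(3L)
  withr::with_seed(41, {
    expr <- matrix(rnorm(50 * 12, mean = 5), 50, 12,
                   dimnames = list(sprintf("g%02d", 1:50), d$sample))
  })
  fit <- fit_gene_models(expr, d)
  eb <- ebayes_moderate(fit)
  de <- contrast_test(eb, "AB_vs_A")

  # step-by-step: per-gene lm -> shrink with (d0, s0^2) -> t
  cellmeans <- t(sapply(rownames(expr), function(g) {
    tapply(expr[g, ], paste0(d$x_A, d$x_B), mean)
  }))[, c("00", "10", "01", "11")]
  s2 <- sapply(rownames(expr), function(g) {
    sum((expr[g, ] - cellmeans[g, match(paste0(d$x_A, d$x_B),
                                        c("00", "10", "01", "11"))])^2) / 8
  })
  s2post <- (eb$d0 * eb$s0_2 + 8 * s2) / (eb$d0 + 8)
  lfc <- cellmeans[, "11"] - cellmeans[, "10"]
  tval <- lfc / sqrt(s2post * (1 / 3 + 1 / 3))
  expect_equal(de$logFC, unname(lfc), tolerance = 1e-10)
  expect_equal(de$t, unname(tval), tolerance = 1e-10)
  expect_equal(de$p, unname(2 * pt(-abs(tval), df = eb$d0 + 8)),
               tolerance = 1e-10)

  # d0 = 0 limit: identical to the ordinary pooled-variance OLS t-test
  de0 <- contrast_test(no_moderation(fit), "AB_vs_A")
  t_ols <- lfc / sqrt(s2 * (2 / 3))
  expect_equal(de0$t, unname(t_ols), tolerance = 1e-10)
  expect_equal(de0$p, unname(2 * pt(-abs(t_ols), df = 8)),
               tolerance = 1e-10)

  # zero contrast: no effect, p = 1
  z <- contrast_test(eb, rep(0, 4), name = "self")
  expect_true(all(z$logFC == 0 & z$p == 1))
})

test_that("full moderated pipeline agrees with the limma reference", {
  library(limma)
  fx <- sim_de_fixture(1L)
  kept <- filter_low_counts(fx$sim$counts)
  expr <- log_cpm(kept)
  cell <- factor(paste0(fx$sim$design$x_A, fx$sim$design$x_B),
                 levels = c("00", "10", "01", "11"),
                 labels = c("ctrl", "A", "B", "AB"))
  X <- model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  lfit <- lmFit(expr, X)
  cm <- makeContrasts(AB_vs_A = AB - A, levels = X)
  lfit2 <- eBayes(contrasts.fit(lfit, cm))
  mine <- fx$de$AB_vs_A
  expect_equal(attr(fx$de, "ebayes")$d0, lfit2$df.prior, tolerance = 1e-8)
  expect_equal(mine$t, unname(lfit2$t[, "AB_vs_A"]), tolerance = 1e-8)
  expect_equal(mine$p, unname(lfit2$p.value[, "AB_vs_A"]),
               tolerance = 1e-8)
})

test_that("interaction contrast equals the cell-mean combination", {
  fx <- sim_de_fixture(1L)
  eb <- attr(fx$de, "ebayes")
  inter <- contrast_test(eb, "interaction")
  b <- eb$fit$coefficients
  expect_equal(inter$logFC,
               unname((b[, "AB"] - b[, "A"]) - (b[, "B"] - b[, "ctrl"])),
               tolerance = 1e-10)
})

test_that("design validation catches malformed tables", {
  d <- make_design()
  d2 <- d; d2$x_A[3] <- 2
  expect_error(validate_design(d2), "row 3")
  d3 <- d; d3$sample[1] <- d3$sample[2]
  expect_error(validate_design(d3), "duplicate")
  expect_error(validate_design(d[, -2]), "columns")
  expect_error(
    fit_gene_models(matrix(0, 2, 8,
                           dimnames = list(c("a", "b"), paste0("x", 1:8))),
                    d),
    "do not match")
})
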