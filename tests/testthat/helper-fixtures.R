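# Shared fixtures, built in code and cached so expensive simulations run
# once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default factorial simulation + DE + DEG sets, reused across files
sim_de_fixture <- function(seed = 1L) {
  cached(paste0("simde_", seed), {
    sim <- gen_factorial_counts(factorial_sim_config(seed = seed))
    de <- run_de(sim$counts, sim$design)
    list(sim = sim, de = de,
         sets = lapply(de[c("AB_vs_A", "B_vs_ctrl", "AB_vs_B",
                            "A_vs_ctrl")], deg_set))
  })
}

# small deterministic expression matrix for rank-based tests
toy_expr <- function(n_genes = 200L, n_samples = 10L, seed = 42L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# independent brute-force single-sample score (sort-based, no rank())
brute_singscore <- function(expr, set) {
  set <- intersect(set, rownames(expr))
  N <- nrow(expr)
  nG <- length(set)
  sapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    # average ranks computed from scratch via the sorted order
    o <- order(x)
    r <- numeric(N)
    k <- 1
    while (k <= N) {
      same <- which(x[o] == x[o[k]])
      r[o[same]] <- mean(same)
      k <- max(same) + 1
    }
    names(r) <- names(x)
    rbar <- mean(r[set])
    rmin <- (nG + 1) / 2
    rmax <- N - (nG - 1) / 2
    (rbar - rmin) / (rmax - rmin) - 0.5
  })
}

# independent brute-force running-sum enrichment score
brute_gsea_es <- function(metric, set, weight = 1) {
  o <- order(metric, decreasing = TRUE)
  m <- metric[o]
  hit <- names(m) %in% set
  N <- length(m)
  NR <- sum(abs(m[hit])^weight)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(m[i])^weight / NR
           else cur - 1 / (N - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
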