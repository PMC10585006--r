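# Synthetic-data generators with planted ground truth: factorial
# negative-binomial counts, survival cohorts, fiber-track populations, and
# tumor growth curves. Every generator draws from a private RNG stream
# derived from its seed, so identical configs give bit-identical outputs
# and the caller's RNG state is untouched.

#' Configuration for the factorial count simulator
#'
#' Defines a 2x2 treatment design (control, A, B, AB) with five gene
#' classes. Counts for gene g in sample s are negative binomial with mean
#' `libsize_s * q_g * 2^(x_A a_g + x_B b_g + x_A x_B i_g)` and variance
#' `mu + phi mu^2`. "Combination-only" genes carry their whole effect in
#' the interaction term (a = b = 0, i != 0), so they are invisible in both
#' monotherapies by construction; "additive" genes respond to both
#' monotherapies with no interaction.
#'
#' Baseline relative abundances q_g are log-uniform over 4 orders of
#' magnitude for null genes (so low-count filtering is exercised) and over
#' the upper 3 orders for planted-effect genes (regulated programs sit in
#' the expressed fraction of the transcriptome).
#'
#' @param n_genes total genes.
#' @param n_reps_per_condition replicates per treatment cell.
#' @param program_sizes named integer vector over
#'   `c("null","A_only","B_only","additive","combo_only")`; must sum to
#'   `n_genes`. Unspecified classes default to 0 with the remainder null.
#' @param effect_lfc named list of log2 effect sizes per class:
#'   `A_only` (a), `B_only` (b), `additive` (c(a, b)), `combo_only` (i).
#'   Defaults: a = b = -2 for the responsive classes and i = -2 (the
#'   treatments repress their targets).
#' @param dispersion either a single phi > 0 or `c(shape, rate)` of a gamma
#'   distribution for per-gene phi (default shape 2, rate 40: mean 0.05,
#'   cell-line-like).
#' @param lib_size_range min/max expected total counts per sample
#'   (default 1e6-2e6).
#' @param seed integer seed.
#' @return list of class `factorial_sim_config`.
#' @export
factorial_sim_config <- function(n_genes = 2000L, n_reps_per_condition = 3L,
                                 program_sizes = c(A_only = 50L,
                                                   B_only = 50L,
                                                   additive = 50L,
                                                   combo_only = 50L),
                                 effect_lfc = list(A_only = -2,
                                                   B_only = -2,
                                                   additive = c(-2, -2),
                                                   combo_only = -2),
                                 dispersion = c(shape = 2, rate = 40),
                                 lib_size_range = c(1e6, 2e6),
                                 seed = 1L) {
  stopifnot(n_genes >= 1, n_reps_per_condition >= 1)
  classes <- c("null", "A_only", "B_only", "additive", "combo_only")
  sizes <- stats::setNames(rep(0L, 5L), classes)
  if (!is.null(names(program_sizes)))
    sizes[names(program_sizes)] <- as.integer(program_sizes)
  if (any(sizes < 0)) stop("program sizes must be >= 0")
  planted <- sum(sizes[classes != "null"])
  if (planted > n_genes) stop("program sizes exceed n_genes")
  sizes["null"] <- if ("null" %in% names(program_sizes))
    sizes["null"] else n_genes - planted
  if (sum(sizes) != n_genes) stop("program sizes must sum to n_genes")
  if (sum(sizes) == 0) stop("all program sizes are zero")
  if (any(unlist(dispersion) <= 0)) stop("dispersion must be > 0")
  if (any(lib_size_range <= 0) || lib_size_range[1] > lib_size_range[2])
    stop("invalid lib_size_range")
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_condition = as.integer(n_reps_per_condition),
                 program_sizes = sizes, effect_lfc = effect_lfc,
                 dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 seed = as.integer(seed)),
            class = "factorial_sim_config")
}

#' Simulate factorial negative-binomial counts with planted truth
#'
#' @param cfg a `factorial_sim_config`.
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (sample, x_A, x_B, time, replicate), `truth` (gene, class, a, b, i and
#'   baseline relative abundance q per gene), and `lib_sizes` (named
#'   expected library size per sample), so expected counts
#'   q_g * lib_s * 2^fold are exactly reconstructible.
#' @export
gen_factorial_counts <- function(cfg) {
  stopifnot(inherits(cfg, "factorial_sim_config"))
  local_seed(cfg$seed, stream = 1L, {
    ng <- cfg$n_genes
    nr <- cfg$n_reps_per_condition
    genes <- sprintf("gene_%05d", seq_len(ng))
    cls <- rep(names(cfg$program_sizes), cfg$program_sizes)
    cls <- sample(cls)                       # interleave classes over genes
    eff <- cfg$effect_lfc
    a <- b <- i <- numeric(ng)
    a[cls == "A_only"] <- (eff$A_only %||% -2)[1]
    b[cls == "B_only"] <- (eff$B_only %||% -2)[1]
    add <- eff$additive %||% c(-2, -2)
    if (length(add) == 1L) add <- c(add, add)
    a[cls == "additive"] <- add[1]
    b[cls == "additive"] <- add[2]
    i[cls == "combo_only"] <- (eff$combo_only %||% -2)[1]

    # baseline relative abundances: nulls span 4 decades, planted-effect
    # genes the top 3
    lo <- ifelse(cls == "null", -5, -4)
    q <- 10^stats::runif(ng, min = lo, max = -1)
    q <- q / sum(q)

    phi <- if (length(cfg$dispersion) == 1L)
      rep(cfg$dispersion, ng)
    else stats::rgamma(ng, shape = cfg$dispersion[[1]],
                       rate = cfg$dispersion[[2]])
    phi <- pmax(phi, 1e-6)

    cells <- data.frame(cell = c("ctrl", "A", "B", "AB"),
                        x_A = c(0, 1, 0, 1), x_B = c(0, 0, 1, 1))
    design <- cells[rep(seq_len(4), each = nr), , drop = FALSE]
    design$replicate <- rep(seq_len(nr), times = 4)
    design$sample <- paste0(design$cell, "_r", design$replicate)
    design$time <- 20
    rownames(design) <- NULL

    lib <- stats::runif(nrow(design), cfg$lib_size_range[1],
                        cfg$lib_size_range[2])
    fold <- outer(a, design$x_A) + outer(b, design$x_B) +
      outer(i, design$x_A * design$x_B)
    mu <- (q %o% lib) * 2^fold
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
                     nrow = ng,
                     dimnames = list(genes, design$sample))
    truth <- data.frame(gene = genes, class = cls, a = a, b = b, i = i,
                        q = q, stringsAsFactors = FALSE)
    list(counts = counts,
         design = design[, c("sample", "x_A", "x_B", "time", "replicate")],
         truth = truth,
         lib_sizes = stats::setNames(lib, design$sample))
  })
}

#' Configuration for the survival-cohort simulator
#'
#' Each patient carries a latent signature-expression factor
#' z ~ Normal(0, latent_effect_sd^2) that shifts the (log-scale) expression
#' of the signature genes; event times are exponential with hazard
#' `baseline_hazard * exp(hazard_coef * z)`, censored administratively at
#' `censor_horizon`. With `hazard_coef > 0`, high signature expression
#' (high score) means worse survival.
#'
#' @param n_patients cohort size (>= 6 so tertiles are non-empty).
#' @param latent_effect_sd spread of z (log2-expression units; default 1).
#' @param hazard_coef log-hazard per unit z (default 1).
#' @param baseline_hazard events per unit time at z = 0 (default 0.01 per
#'   month, giving a median of about 69 months).
#' @param censor_horizon administrative censoring time (default 96 months,
#'   an 8-year follow-up).
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 62L, latent_effect_sd = 1,
                              hazard_coef = 1, baseline_hazard = 0.01,
                              censor_horizon = 96, seed = 1L) {
  stopifnot(n_patients >= 6, latent_effect_sd >= 0,
            baseline_hazard > 0, censor_horizon > 0)
  structure(list(n_patients = as.integer(n_patients),
                 latent_effect_sd = latent_effect_sd,
                 hazard_coef = hazard_coef,
                 baseline_hazard = baseline_hazard,
                 censor_horizon = censor_horizon,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate an expression + survival cohort tied to a signature
#'
#' @param cfg a `cohort_sim_config`.
#' @param gene_universe character vector of all gene ids in the expression
#'   matrix.
#' @param signature_genes character vector, subset of `gene_universe`,
#'   whose expression tracks the latent factor.
#' @return list with `expr` (genes x patients, log2-scale), `survival`
#'   (sample, time, event), `latent` (named z per patient).
#' @export
gen_patient_cohort <- function(cfg, gene_universe, signature_genes) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  if (length(signature_genes) == 0L) stop("empty signature set")
  if (!all(signature_genes %in% gene_universe))
    stop("signature genes must be contained in the gene universe")
  local_seed(cfg$seed, stream = 2L, {
    np <- cfg$n_patients
    ng <- length(gene_universe)
    pats <- sprintf("pt_%03d", seq_len(np))
    z <- stats::rnorm(np, 0, cfg$latent_effect_sd)
    base <- stats::rnorm(ng, mean = 7, sd = 2)      # per-gene baseline
    noise <- matrix(stats::rnorm(ng * np, 0, 1), ng, np)
    expr <- base + noise
    in_sig <- gene_universe %in% signature_genes
    expr[in_sig, ] <- expr[in_sig, ] + rep(z, each = sum(in_sig))
    dimnames(expr) <- list(gene_universe, pats)
    rate <- cfg$baseline_hazard * exp(cfg$hazard_coef * z)
    t_event <- stats::rexp(np, rate = rate)
    time <- pmin(t_event, cfg$censor_horizon)
    event <- as.integer(t_event <= cfg$censor_horizon)
    list(expr = expr,
         survival = data.frame(sample = pats, time = time, event = event,
                               stringsAsFactors = FALSE),
         latent = stats::setNames(z, pats))
  })
}

#' Configuration for the fiber-population simulator
#'
#' One condition's track population. Structures are green-only with
#' probability `class_mix["green_only"]`; the remaining (red-containing)
#' structures are first-label origins (green-red-green) with probability
#' `origin_fraction`, red-only (terminated forks) with probability
#' `class_mix["red_only"]` rescaled among red-containing structures, and
#' ongoing (red-green) forks otherwise. Fork speeds are lognormal around
#' `median_speed_kb_min`; each labeled track length is
#' `speed * pulse_min / kb_per_um` micrometres.
#'
#' @param median_speed_kb_min median fork speed, kb/min (default 1.0).
#' @param speed_sdlog log-scale sd of fork speed (default 0.3).
#' @param origin_fraction P(first-label origin | red-containing)
#'   (default 0.15).
#' @param class_mix named probabilities `red_only` and `green_only` of all
#'   structures (defaults 0.1 and 0.15).
#' @param n_structures structures to generate (default 500).
#' @param condition,replicate labels attached to every structure.
#' @param params an `assay_params`.
#' @param seed integer seed.
#' @return list of class `fiber_sim_config`.
#' @export
fiber_sim_config <- function(median_speed_kb_min = 1.0, speed_sdlog = 0.3,
                             origin_fraction = 0.15,
                             class_mix = c(red_only = 0.1,
                                           green_only = 0.15),
                             n_structures = 500L, condition = "control",
                             replicate = "1", params = assay_params(),
                             seed = 1L) {
  stopifnot(median_speed_kb_min > 0, speed_sdlog >= 0, n_structures >= 1)
  p_go <- class_mix[["green_only"]]
  p_ro <- class_mix[["red_only"]]
  if (any(c(p_go, p_ro, origin_fraction) < 0) ||
      any(c(p_go, p_ro, origin_fraction) > 1))
    stop("probabilities must lie in [0, 1]")
  # among red-containing structures: origin_fraction GRG, then red-only,
  # then ongoing forks; the three must be a proper mixture
  p_ro_given_red <- if (p_go < 1) p_ro / (1 - p_go) else 0
  if (origin_fraction + p_ro_given_red > 1)
    stop("class_mix and origin_fraction are inconsistent (mixture exceeds 1)")
  structure(list(median_speed_kb_min = median_speed_kb_min,
                 speed_sdlog = speed_sdlog,
                 origin_fraction = origin_fraction,
                 class_mix = c(red_only = p_ro, green_only = p_go),
                 n_structures = as.integer(n_structures),
                 condition = condition, replicate = replicate,
                 params = params, seed = as.integer(seed)),
            class = "fiber_sim_config")
}

#' Simulate a population of labeled fiber structures
#'
#' @param cfg a `fiber_sim_config`.
#' @return list of `fiber_structure`s.
#' @export
gen_fiber_set <- function(cfg) {
  stopifnot(inherits(cfg, "fiber_sim_config"))
  local_seed(cfg$seed, stream = 3L, {
    n <- cfg$n_structures
    p_go <- cfg$class_mix[["green_only"]]
    p_ro_given_red <- if (p_go < 1)
      cfg$class_mix[["red_only"]] / (1 - p_go) else 0
    p_grg <- cfg$origin_fraction
    u <- stats::runif(n)
    red_containing <- u >= p_go
    v <- stats::runif(n)
    cls <- ifelse(!red_containing, "second_label_only",
           ifelse(v < p_grg, "first_label_origin",
           ifelse(v < p_grg + p_ro_given_red, "terminated_fork",
                  "ongoing_fork")))
    pr <- cfg$params
    mul <- log(cfg$median_speed_kb_min)
    seg_len <- function(k, pulse_min) {
      speed <- stats::rlnorm(k, meanlog = mul, sdlog = cfg$speed_sdlog)
      speed * pulse_min / pr$kb_per_um
    }
    lapply(seq_len(n), function(j) {
      id <- sprintf("%s_%s_f%05d", cfg$condition, cfg$replicate, j)
      segs <- switch(cls[j],
        second_label_only = list(colors = "green",
                                 lengths = seg_len(1, pr$pulse2_min)),
        terminated_fork = list(colors = "red",
                               lengths = seg_len(1, pr$pulse1_min)),
        ongoing_fork = list(colors = c("red", "green"),
                            lengths = c(seg_len(1, pr$pulse1_min),
                                        seg_len(1, pr$pulse2_min))),
        first_label_origin = list(
          colors = c("green", "red", "green"),
          lengths = c(seg_len(1, pr$pulse2_min),
                      seg_len(1, pr$pulse1_min),
                      seg_len(1, pr$pulse2_min))))
      fiber_structure(segs$colors, segs$lengths, fiber_id = id,
                      condition = cfg$condition, replicate = cfg$replicate)
    })
  })
}

#' Simulate tumor caliper growth curves
#'
#' Per tumor, volume follows exponential growth from a baseline volume,
#' multiplied by lognormal measurement noise; volumes are converted back to
#' width/length pairs at a fixed aspect ratio so that
#' `tumor_volume(width, length)` recovers the simulated volume exactly.
#'
#' @param groups named numeric vector: per-group exponential growth rate
#'   (per day).
#' @param n_tumors tumors per group.
#' @param days measurement days, sorted ascending; the first is baseline.
#' @param baseline_volume_mm3 volume at baseline (default 150).
#' @param noise_sd lognormal (log-scale) measurement noise sd (default
#'   0.1; baseline is noise-free so normalization is exact at day 0).
#' @param aspect_ratio length/width (default 1.5).
#' @param seed integer seed.
#' @return data.frame: group, tumor_id, day, width_mm, length_mm.
#' @export
gen_growth_curves <- function(groups, n_tumors = 8L,
                              days = c(0, 2, 4, 6, 8),
                              baseline_volume_mm3 = 150, noise_sd = 0.1,
                              aspect_ratio = 1.5, seed = 1L) {
  stopifnot(!is.null(names(groups)), n_tumors >= 1,
            !is.unsorted(days), baseline_volume_mm3 > 0, noise_sd >= 0,
            aspect_ratio > 0)
  local_seed(seed, stream = 4L, {
    rows <- list()
    for (g in names(groups)) {
      for (k in seq_len(n_tumors)) {
        id <- sprintf("%s_t%02d", g, k)
        noise <- c(0, stats::rnorm(length(days) - 1L, 0, noise_sd))
        vol <- baseline_volume_mm3 *
          exp(groups[[g]] * (days - days[1])) * exp(noise)
        width <- (2 * vol / aspect_ratio)^(1 / 3)
        rows[[id]] <- data.frame(group = g, tumor_id = id, day = days,
                                 width_mm = width,
                                 length_mm = aspect_ratio * width,
                                 stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
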