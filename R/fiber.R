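# Single-molecule DNA-fiber replication dynamics: classify dual-pulse
# (red = first label, CldU; green = second label, IdU) track patterns,
# estimate fork rates from the green track of ongoing forks, and estimate
# origin-firing frequency as the percentage of first-label-origin
# (green-red-green) structures among red-containing structures.

#' Fiber-assay physical parameters
#'
#' @param kb_per_um DNA content per micrometre of stretched fiber
#'   (default 2.59 kb/um, the standard conversion).
#' @param pulse1_min duration of the first (red, CldU) pulse in minutes
#'   (default 20).
#' @param pulse2_min duration of the second (green, IdU) pulse in minutes
#'   (default 20).
#' @return list of class `assay_params`.
#' @export
assay_params <- function(kb_per_um = 2.59, pulse1_min = 20,
                         pulse2_min = 20) {
  stop_if_not_scalar_pos(kb_per_um, "kb_per_um")
  stop_if_not_scalar_pos(pulse1_min, "pulse1_min")
  stop_if_not_scalar_pos(pulse2_min, "pulse2_min")
  structure(list(kb_per_um = kb_per_um, pulse1_min = pulse1_min,
                 pulse2_min = pulse2_min), class = "assay_params")
}

#' One labeled fiber structure
#'
#' Ordered colored segments along one DNA fiber. Adjacent same-color
#' segments are merged on construction (their lengths summed), matching
#' how contiguous tracks are measured.
#'
#' @param colors character vector in `{"red", "green"}`, in fiber order.
#' @param lengths_um positive segment lengths, micrometres.
#' @param fiber_id identifier.
#' @param condition,replicate optional labels.
#' @return list of class `fiber_structure`.
#' @export
fiber_structure <- function(colors, lengths_um, fiber_id = NA_character_,
                            condition = NA_character_,
                            replicate = NA_character_) {
  if (length(colors) == 0L) stop("empty structure")
  if (length(colors) != length(lengths_um)) stop("colors/lengths mismatch")
  if (!all(colors %in% c("red", "green")))
    stop("unknown segment color (must be red or green)")
  if (any(!is.finite(lengths_um)) || any(lengths_um <= 0))
    stop("segment lengths must be positive")
  # merge adjacent same-color segments
  grp <- cumsum(c(TRUE, colors[-1] != colors[-length(colors)]))
  colors <- colors[!duplicated(grp)]
  lengths_um <- as.numeric(tapply(lengths_um, grp, sum))
  structure(list(fiber_id = fiber_id, colors = colors,
                 lengths_um = lengths_um, condition = condition,
                 replicate = replicate), class = "fiber_structure")
}

#' Classify a fiber structure into a replication pattern class
#'
#' Pattern matching on the color sequence, invariant to reading direction
#' (stretched fibers have no intrinsic orientation):
#' red only = terminated fork; red-green (either order) = ongoing fork;
#' green-red-green = first-label origin (fired during the first pulse);
#' green only = second-label only; anything else (>3 segments, e.g. sister
#' forks on one fiber) = ambiguous.
#'
#' @param s a `fiber_structure`.
#' @return one of `"terminated_fork"`, `"ongoing_fork"`,
#'   `"first_label_origin"`, `"second_label_only"`, `"ambiguous"`.
#' @export
classify_structure <- function(s) {
  stopifnot(inherits(s, "fiber_structure"))
  key <- paste(substr(s$colors, 1, 1), collapse = "")
  switch(key,
    r = "terminated_fork",
    g = "second_label_only",
    rg = , gr = "ongoing_fork",
    grg = "first_label_origin",
    "ambiguous")
}

#' Fork rates from ongoing-fork structures
#'
#' One rate per ongoing (red-green) fork: the green (second-label) track
#' length converted to kb and divided by the second pulse duration; red
#' track length is used only for classification. Other structure classes
#' are excluded.
#'
#' @param structures list of `fiber_structure`s.
#' @param params an `assay_params` (default: 2.59 kb/um, 20-min pulses).
#' @return data.frame: fiber_id, condition, replicate, green_um,
#'   rate_kb_per_min.
#' @export
fork_rates <- function(structures, params = assay_params()) {
  stopifnot(inherits(params, "assay_params"))
  rows <- lapply(structures, function(s) {
    if (classify_structure(s) != "ongoing_fork") return(NULL)
    green <- sum(s$lengths_um[s$colors == "green"])
    data.frame(fiber_id = s$fiber_id, condition = s$condition,
               replicate = s$replicate, green_um = green,
               rate_kb_per_min = green * params$kb_per_um /
                 params$pulse2_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fiber_id = character(0), condition = character(0),
                      replicate = character(0), green_um = numeric(0),
                      rate_kb_per_min = numeric(0))
  out
}

#' Origin-firing percentage
#'
#' The percentage of first-label-origin (green-red-green) structures among
#' all structures containing at least one red track (ongoing forks,
#' first-label origins, terminated forks, and red-containing ambiguous
#' structures; the latter are also counted separately).
#'
#' @param structures list of `fiber_structure`s.
#' @return list with `numerator`, `denominator`, `percentage`,
#'   `n_ambiguous_red` (red-containing ambiguous structures included in the
#'   denominator).
#' @export
origin_firing_pct <- function(structures) {
  cls <- vapply(structures, classify_structure, character(1))
  has_red <- vapply(structures, function(s) "red" %in% s$colors, logical(1))
  den <- sum(has_red)
  if (den == 0L) stop("no red-containing structures")
  num <- sum(cls == "first_label_origin")
  list(numerator = num, denominator = den,
       percentage = 100 * num / den,
       n_ambiguous_red = sum(has_red & cls == "ambiguous"))
}

#' Compare replication dynamics across conditions
#'
#' Fork rates (pooled tracks per condition) are compared by Kruskal-Wallis
#' plus Dunn's post-test; origin-firing percentages (one value per
#' replicate) are compared by one-way ANOVA across conditions, reported as
#' not testable when any condition has a single replicate or the residual
#' degrees of freedom vanish.
#'
#' @param structures list of `fiber_structure`s carrying `condition` and
#'   `replicate` labels.
#' @param params an `assay_params`.
#' @return list with `fork`: (medians per condition, kruskal, dunn) and
#'   `origin`: (per-replicate percentages, anova or status
#'   `"not testable"`).
#' @export
compare_conditions <- function(structures, params = assay_params()) {
  conds <- vapply(structures, `[[`, character(1), "condition")
  if (length(unique(conds)) < 2L) stop("need at least 2 conditions")
  fr <- fork_rates(structures, params)
  fork_groups <- split(fr$rate_kb_per_min, fr$condition)
  kw <- kruskal_wallis(fork_groups)
  dunn <- dunn_posttest(fork_groups)
  reps <- vapply(structures, `[[`, character(1), "replicate")
  key <- paste(conds, reps, sep = "\r")
  origin_rows <- lapply(split(structures, key), function(ss) {
    est <- origin_firing_pct(ss)
    data.frame(condition = ss[[1]]$condition, replicate = ss[[1]]$replicate,
               percentage = est$percentage, stringsAsFactors = FALSE)
  })
  origin_df <- do.call(rbind, origin_rows)
  rownames(origin_df) <- NULL
  origin_groups <- split(origin_df$percentage, origin_df$condition)
  origin <- list(per_replicate = origin_df)
  if (any(lengths(origin_groups) < 2L) ||
      sum(lengths(origin_groups)) - length(origin_groups) < 1L) {
    origin$status <- "not testable"
  } else {
    origin$anova <- anova_oneway(origin_groups)
    origin$status <- origin$anova$status
  }
  list(fork = list(medians = vapply(fork_groups, stats::median, numeric(1)),
                   n = lengths(fork_groups), kruskal = kw, dunn = dunn),
       origin = origin)
}
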