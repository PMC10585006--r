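# Kaplan-Meier product-limit estimation, the two-group log-rank test, and
# the cohort stratification report (score -> tertiles -> extreme-tertile
# survival comparison).

#' Validate survival records
#'
#' @param records data.frame with columns `sample`, `time` (>= 0, finite)
#'   and `event` (0 = censored, 1 = event).
#' @return the validated data.frame.
#' @export
validate_survival <- function(records) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(records)))
    stop("survival records need columns sample, time, event")
  if (any(!is.finite(records$time)) || any(records$time < 0))
    stop("times must be finite and non-negative")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (anyDuplicated(records$sample)) stop("duplicate sample ids")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records survival records (see [validate_survival()]).
#' @return data.frame of class `km_curve`: columns time (distinct event
#'   times, ascending), n_risk (at-risk count just before each), n_event,
#'   surv (survival probability just after each). S is 1 before the first
#'   event; censored times reduce the risk set without steps.
#' @export
km_estimate <- function(records) {
  records <- validate_survival(records)
  if (nrow(records) == 0L) stop("no records")
  tt <- sort(unique(records$time[records$event == 1]))
  if (length(tt) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
  } else {
    n_risk <- vapply(tt, function(t) sum(records$time >= t), numeric(1))
    n_event <- vapply(tt, function(t)
      sum(records$time == t & records$event == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                      surv = surv)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at given times from a Kaplan-Meier curve
#'
#' @param km a `km_curve`.
#' @param times numeric vector of evaluation times.
#' @return S(t) for each time (right-continuous step function).
#' @export
km_surv_at <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  vapply(times, function(t) {
    i <- which(km$time <= t)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the pooled risk set;
#' the squared standardized sum is referred to chi-square on 1 df.
#'
#' @param groupA,groupB survival-record data.frames.
#' @return list with `chisq`, `df` (1), `p`, `observed` and `expected`
#'   event counts per group. With no events at all, p = 1 with a warning.
#' @export
logrank_test <- function(groupA, groupB) {
  groupA <- validate_survival(groupA)
  groupB <- validate_survival(groupB)
  if (nrow(groupA) == 0L || nrow(groupB) == 0L) stop("empty group")
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  inA <- rep(c(TRUE, FALSE), c(nrow(groupA), nrow(groupB)))
  tt <- sort(unique(time[event == 1]))
  if (length(tt) == 0L) {
    warning("no events in either group; log-rank p set to 1")
    return(list(chisq = 0, df = 1L, p = 1,
                observed = c(A = 0, B = 0), expected = c(A = 0, B = 0)))
  }
  O <- E <- V <- 0
  OB <- EB <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nA <- sum(at_risk & inA)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & inA)
    O <- O + dA
    E <- E + d * nA / n
    OB <- OB + (d - dA)
    EB <- EB + d * (n - nA) / n
    if (n > 1)
      V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = c(A = O, B = OB), expected = c(A = E, B = EB))
}

#' Score a cohort, stratify into tertiles, and compare extreme tertiles
#'
#' The full patient-stratification analysis: rank-based signature scores
#' per sample, tertile assignment, Kaplan-Meier curves for the bottom and
#' top tertiles (middle excluded), and the log-rank test between them.
#' When a second gene set is supplied, the Pearson and Spearman
#' correlations between the two sets' scores are also reported.
#'
#' @param expr genes x samples expression matrix.
#' @param gene_set character vector of signature genes.
#' @param survival survival records matching the expression samples.
#' @param gene_set2 optional second gene set for score correlation.
#' @return list with `scores`, `tertiles`, `km_bottom`, `km_top`,
#'   `logrank` (top vs bottom), and optionally `score_correlation`
#'   (pearson, spearman).
#' @export
stratify_and_compare <- function(expr, gene_set, survival,
                                 gene_set2 = NULL) {
  survival <- validate_survival(survival)
  if (!all(survival$sample %in% colnames(expr)))
    stop("survival sample ids missing from the expression matrix")
  expr <- expr[, survival$sample, drop = FALSE]
  sc <- singscore(expr, gene_set)
  tert <- assign_tertiles(sc)
  pick <- function(level)
    survival[survival$sample %in% tert$sample[tert$tertile == level], ,
             drop = FALSE]
  bottom <- pick("bottom")
  top <- pick("top")
  out <- list(scores = sc, tertiles = tert,
              km_bottom = km_estimate(bottom),
              km_top = km_estimate(top),
              logrank = logrank_test(top, bottom))
  if (!is.null(gene_set2)) {
    sc2 <- singscore(expr, gene_set2)
    out$score_correlation <- c(
      pearson = correlation(sc$score, sc2$score, "pearson"),
      spearman = correlation(sc$score, sc2$score, "spearman"))
    out$scores2 <- sc2
  }
  out
}
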