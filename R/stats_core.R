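# Shared statistical primitives, implemented from their defining formulas.
# Base-R equivalents (p.adjust, kruskal.test, aov, cor) are used as
# independent cross-checks in the test suite, never as the implementation.

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg false-discovery-rate step-up procedure:
#' after sorting ascending, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, then restored to the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\]. Names are preserved.
#' @return numeric vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  names(out) <- names(p)
  out
}

# Average ranks and the tie-correction sum T = sum(t^3 - t) over tied groups.
.rank_with_ties <- function(x) {
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  t3 <- sum(tab^3 - tab)
  list(ranks = r, tie_sum = t3)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based k-group location test with the standard tie correction
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; the statistic is referred to a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups named list of numeric vectors, one per group.
#' @return list with `H`, `df`, `p`, and per-group mean ranks.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("observations must be finite")
  n <- lengths(groups)
  N <- sum(n)
  if (N < 2L) stop("need at least 2 observations in total")
  rk <- .rank_with_ties(x)
  g <- rep.int(seq_len(k), n)
  rsum <- tapply(rk$ranks, g, sum)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / n) - 3 * (N + 1)
  corr <- 1 - rk$tie_sum / (N^3 - N)
  if (corr <= 0) {            # all observations identical
    H <- 0
    p <- 1
  } else {
    H <- H / corr
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  list(H = H, df = k - 1L, p = p,
       mean_ranks = stats::setNames(as.numeric(rsum / n),
                                    names(groups) %||% seq_len(k)))
}

#' Dunn's post-hoc test on joint ranks
#'
#' Pairwise z-tests following a Kruskal-Wallis analysis,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 -
#' \sum(t^3-t)/(12(N-1))) (1/n_i + 1/n_j)}} on the joint ranks, with
#' two-sided normal p-values adjusted over the comparisons actually
#' performed.
#'
#' @param groups named list of numeric vectors.
#' @param comparisons optional list of length-2 character vectors naming the
#'   pairs to test; default all pairs.
#' @param adjustment `"bonferroni"` (default, matching common post-test
#'   software) or `"holm"`.
#' @return data.frame with columns group1, group2, z, p, adj_p.
#' @export
dunn_posttest <- function(groups, comparisons = NULL,
                          adjustment = c("bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(lengths(groups) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  rk <- .rank_with_ties(x)
  g <- rep.int(names(groups), n)
  rbar <- tapply(rk$ranks, g, mean)[names(groups)]
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2L, simplify = FALSE)
  }
  vfac <- N * (N + 1) / 12 - rk$tie_sum / (12 * (N - 1))
  res <- lapply(comparisons, function(pr) {
    if (!all(pr %in% names(groups))) stop("unknown group in comparison")
    se <- sqrt(vfac * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- if (se > 0) (rbar[[pr[1]]] - rbar[[pr[2]]]) / se else 0
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- switch(adjustment,
    bonferroni = pmin(out$p * nrow(out), 1),
    holm = {
      m <- nrow(out); o <- order(out$p)
      adj <- cummax(pmin(out$p[o] * (m - seq_len(m) + 1L), 1))
      r <- numeric(m); r[o] <- adj; r
    })
  out
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly applies the two-sided Grubbs test: the most extreme value is
#' removed when \eqn{G = \max|x - \bar x| / s} exceeds
#' \eqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{t^2 / (n - 2 + t^2)}} with
#' \eqn{t} the upper \eqn{\alpha/(2n)} quantile of the t-distribution on
#' n - 2 df, stopping when no value is flagged, fewer than 3 values remain,
#' or `max_removals` is reached.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level per iteration (default 0.1).
#' @param max_removals maximum values removed (default 2).
#' @return list with `kept` and `removed` numeric vectors.
#' @export
grubbs_iterative <- function(values, alpha = 0.1, max_removals = 2L) {
  stopifnot(is.numeric(values), alpha > 0, alpha < 1)
  if (length(values) < 3L) stop("need at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  kept <- values
  removed <- numeric(0)
  while (length(removed) < max_removals && length(kept) >= 3L) {
    n <- length(kept)
    s <- stats::sd(kept)
    if (s == 0) break
    dev <- abs(kept - mean(kept))
    i <- which.max(dev)
    G <- dev[i] / s
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    Gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G > Gcrit) {
      removed <- c(removed, kept[i])
      kept <- kept[-i]
    } else break
  }
  list(kept = kept, removed = removed)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio with an F-distribution
#' p-value. Degenerate inputs (zero residual degrees of freedom or zero
#' within-group variance) are reported via the `status` field rather than
#' erroring.
#'
#' @param groups named list of numeric vectors.
#' @return list with `F`, `df1`, `df2`, `p`, group means, and `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  n <- lengths(groups)
  N <- sum(n)
  if (N - k < 1L) stop("zero residual degrees of freedom")
  x <- unlist(groups, use.names = FALSE)
  gm <- vapply(groups, mean, numeric(1))
  grand <- mean(x)
  ss_between <- sum(n * (gm - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  ms_b <- ss_between / (k - 1)
  ms_w <- ss_within / (N - k)
  if (ms_w == 0) {
    return(list(F = if (ms_b == 0) 0 else Inf, df1 = k - 1L, df2 = N - k,
                p = if (ms_b == 0) 1 else 0, means = gm,
                status = "degenerate"))
  }
  Fstat <- ms_b / ms_w
  list(F = Fstat, df1 = k - 1L, df2 = N - k,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       means = gm, status = "ok")
}

#' Pearson or Spearman correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("zero variance")
  sum(dx * dy) / sqrt(vx * vy)
}
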