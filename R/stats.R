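#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table
#' (event / non-event counts in two groups), computed by full hypergeometric
#' enumeration with the point-probability rule: the p-value is the sum of
#' the probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table.
#'
#' @param a,b,c,d counts: `a` events and `b` non-events in group 1, `c`
#'   events and `d` non-events in group 2. Alternatively `a` may be a
#'   length-4 vector or 2x2 matrix.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(1, 799, 12, 988)   # transient-deficit event counts
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- as.vector(a)
    stopifnot(length(x) == 4)
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  m <- a + b          # group-1 margin
  n <- c + d          # group-2 margin
  k <- a + c          # event margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margins: p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  # tolerance guards ties against floating-point noise
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

#' Two-stage adaptive FDR control (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage 1 runs a Benjamini-
#' Hochberg step-up at level `q' = Q/(1+Q)`; the number of stage-1
#' rejections r1 estimates the number of true nulls as `m0 = m - r1`;
#' stage 2 re-runs the step-up at level `q' * m / m0`. Adjusted q-values
#' are the smallest `Q` at which each hypothesis would be rejected by the
#' whole two-stage procedure.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param Q target false discovery rate (default 0.05).
#' @return An object of class `bky_fdr`: list with `p`, `Q`, `reject`
#'   (logical), `qvalue`, and `stage1_rejections`.
#' @export
bky_fdr <- function(p, Q = 0.05) {
  if (length(p) == 0)
    return(structure(list(p = numeric(0), Q = Q, reject = logical(0),
                          qvalue = numeric(0), stage1_rejections = 0L),
                     class = "bky_fdr"))
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must be in [0, 1]")
  m <- length(p)

  bh_rejections <- function(p, level) {
    ord <- sort(p)
    ok <- which(ord <= level * seq_len(m) / m)
    if (length(ok)) max(ok) else 0L
  }
  two_stage_reject <- function(p, Q) {
    qp <- Q / (1 + Q)
    r1 <- bh_rejections(p, qp)
    if (r1 == 0L) return(rep(FALSE, m))
    if (r1 == m)  return(rep(TRUE, m))
    r2 <- bh_rejections(p, qp * m / (m - r1))
    rank(p, ties.method = "min") <= r2
  }

  reject <- two_stage_reject(p, Q)
  # q-value: smallest Q at which hypothesis i is rejected (bisection;
  # rejection is monotone in Q for this procedure over a fine grid)
  qvalue <- vapply(seq_len(m), function(i) {
    lo <- 0; hi <- 1
    if (!two_stage_reject(p, 1 - 1e-12)[i]) return(1)
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      if (two_stage_reject(p, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))

  qp <- Q / (1 + Q)
  structure(list(p = p, Q = Q, reject = reject, qvalue = qvalue,
                 stage1_rejections = bh_rejections(p, qp)),
            class = "bky_fdr")
}

#' @export
print.bky_fdr <- function(x, ...) {
  cat("Two-stage FDR (Q =", x$Q, "):", sum(x$reject), "of", length(x$p),
      "hypotheses rejected\n")
  invisible(x)
}

#' Detect transient motor-deficit events in a weekly score series
#'
#' A transient deficit at week t is an abrupt more-than-3-fold decrease of
#' the weekly median test score relative to the previous week, resolving by
#' the next weekly test: `score[t] < score[t-1]/3` and
#' `score[t+1] >= score[t-1]/3`. Since tests are weekly, "recovery within 7
#' days" is recovery at the next observation.
#'
#' @param scores numeric vector of weekly median scores for one animal.
#' @param animal optional id recorded in the output.
#' @param fold drop factor defining a deficit (default 3).
#' @return data.frame with one row per event: `animal`, `week` (index of
#'   the drop week), `pre`, `drop`, `recovery` medians.
#' @examples
#' detect_transient_deficits(c(60, 60, 15, 55, 60))  # one event at week 3
#' @export
detect_transient_deficits <- function(scores, animal = NA, fold = 3) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 weeks of scores")
  ev <- list()
  for (t in 2:(n - 1)) {
    tri <- scores[(t - 1):(t + 1)]
    if (anyNA(tri)) {
      warning("missing score in weeks ", t - 1, "-", t + 1,
              ": triplet skipped")
      next
    }
    line <- tri[1] / fold
    if (tri[2] < line && tri[3] >= line)
      ev[[length(ev) + 1]] <- data.frame(animal = animal, week = t,
                                         pre = tri[1], drop = tri[2],
                                         recovery = tri[3])
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(animal = character(0), week = integer(0), pre = numeric(0),
                  drop = numeric(0), recovery = numeric(0))
}

#' Bias-corrected sample excess kurtosis
#'
#' The fourth standardized moment minus 3, with the standard small-sample
#' bias correction. Negative values indicate a platykurtic
#' distribution (lighter tails than normal), the regime in which a median
#' is preferred over a mean as a within-band summary.
#'
#' @param x numeric vector, n >= 4.
#' @return excess kurtosis; `NA` (with a warning) if the variance is zero.
#' @export
excess_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  s2 <- var(x)
  if (s2 == 0) {
    warning("zero variance: kurtosis undefined")
    return(NA_real_)
  }
  m4 <- sum((x - mean(x))^4) / n
  g2 <- m4 / (sum((x - mean(x))^2) / n)^2 - 3
  # bias-corrected (G2)
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Per-band group comparison of coherence summaries
#'
#' Compares per-animal median band coherences between two groups, band by
#' band, with a two-sample location test, and controls the FDR across
#' bands with the two-stage procedure ([bky_fdr()]). The default test is
#' rank-based (Wilcoxon), a robust choice for the platykurtic coherence
#' summaries; Welch's t-test is available as an alternative.
#'
#' @param x,y data.frames (or matrices) of per-animal band summaries, one
#'   row per animal, one column per band (same column names in both
#'   groups).
#' @param Q FDR level.
#' @param test `"wilcox"` or `"welch"`.
#' @return data.frame with band, group means, p, q, and rejection flag.
#' @export
compare_bands <- function(x, y, Q = 0.05, test = c("wilcox", "welch")) {
  test <- match.arg(test)
  x <- as.data.frame(x); y <- as.data.frame(y)
  stopifnot(identical(colnames(x), colnames(y)))
  if (nrow(x) < 2 || nrow(y) < 2) stop("need at least 2 animals per group")
  p <- vapply(colnames(x), function(b) {
    xi <- x[[b]]; yi <- y[[b]]
    if (var(c(xi, yi)) == 0) return(1)
    if (test == "wilcox")
      suppressWarnings(wilcox.test(xi, yi, exact = FALSE))$p.value
    else t.test(xi, yi)$p.value
  }, numeric(1))
  fdr <- bky_fdr(unname(p), Q)
  data.frame(band = colnames(x), mean_x = colMeans(x), mean_y = colMeans(y),
             p = unname(p), q = fdr$qvalue, significant = fdr$reject,
             row.names = NULL)
}
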