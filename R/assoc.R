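#' Association statistics toolkit
#'
#' Nonparametric statistics used downstream of heterogeneity scoring:
#' tie-aware Spearman correlation with a t-approximation p-value, one-tailed
#' Mann-Whitney U tests (exact by enumeration for small tie-free groups),
#' score tertiles, Kaplan-Meier curves and the two-group log-rank test.
#' All p-values are reported raw; [bh_adjust()] is available but never
#' applied implicitly, mirroring the raw-p-with-star-thresholds reporting
#' convention.
#'
#' @name association-stats
#' @keywords internal
NULL

#' Spearman rank correlation with t-approximation p-value
#'
#' Pairs with any missing value are dropped. rho is the Pearson correlation
#' of average ranks (tie-aware); the two-sided p-value comes from
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom,
#' the standard large-sample approximation used by common statistics
#' packages for cohort-sized n.
#'
#' @param x,y numeric vectors of equal length.
#' @return object of class `correlation_result`: list with `rho`,
#'   `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' One-tailed Mann-Whitney U test
#'
#' U is computed from average ranks. The p-value is exact (full enumeration
#' of the null rank distribution) when both groups have at most `exact_max`
#' observations and no ties are present; otherwise the normal approximation
#' with tie and continuity correction is used. The direction must be stated
#' explicitly: `"greater"` tests whether `a` is stochastically larger
#' than `b`.
#'
#' @param a,b numeric vectors (missing values dropped).
#' @param alternative `"greater"` or `"less"`; no default.
#' @param exact_max exactness threshold on each group size (default 10).
#' @return object of class `group_comparison`: list with `u_statistic`,
#'   `p_value`, `n1`, `n2`, `alternative`, `exact`.
#' @export
mann_whitney <- function(a, b, alternative, exact_max = 10L) {
  alternative <- match.arg(alternative, c("greater", "less"))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && n1 <= exact_max && n2 <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
                 n1 = n1, n2 = n2, alternative = alternative,
                 exact = use_exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, one-tailed (%s) p = %.3g (n1 = %d, n2 = %d, %s)\n",
              x$u_statistic, x$alternative, x$p_value, x$n1, x$n2,
              if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Thin wrapper over [stats::p.adjust()]; provided for completeness and
#' never applied implicitly by any other function in the package.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Split samples into score tertiles
#'
#' Samples are sorted ascending by score, ties broken by stable input
#' order; the lowest `floor(n/3)` are labelled `"low"`, the highest
#' `floor(n/3)` `"high"`, and the remainder `"middle"`. Missing scores get
#' a missing label.
#'
#' @param scores numeric vector (at least 3 non-missing values).
#' @return factor with levels `low`, `middle`, `high`, aligned with the
#'   input.
#' @export
tertile_groups <- function(scores) {
  ok <- which(!is.na(scores))
  n <- length(ok)
  if (n < 3L) stop("need at least 3 non-missing scores")
  if (length(unique(scores[ok])) < n)
    warning("tied scores split by stable input order")
  k <- n %/% 3L
  ord <- ok[order(scores[ok])]   # stable for ties
  lab <- rep(NA_character_, length(scores))
  lab[ord] <- "middle"
  lab[ord[seq_len(k)]] <- "low"
  lab[ord[seq.int(n - k + 1L, n)]] <- "high"
  factor(lab, levels = c("low", "middle", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]. Censored-only data
#' yield a flat curve at 1.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event occurred, 0 = censored.
#' @return object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, plus the underlying `survfit` fit.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop("need at least one record")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event values must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time point(s), %d event(s)\n",
              length(x$time), sum(x$n_event)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time", ylab = "survival probability",
                          ...) {
  plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic via [survival::survdiff()]: at each distinct
#' event time the hypergeometric expectation and variance of group-1 events
#' given the margins; the chi-square statistic has 1 degree of freedom.
#'
#' @param time,event as in [kaplan_meier()].
#' @param group a two-level grouping vector.
#' @return object of class `logrank_result`: list with `chi_square`,
#'   `p_value`, `observed`, `expected` (per group), `n`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (sum(event) < 1) stop("no events in either group")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  structure(list(chi_square = unname(sd_$chisq), p_value = p,
                 observed = sd_$obs, expected = sd_$exp,
                 n = as.vector(table(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank chi-square = %.4f (1 df), p = %.3g\n",
              x$chi_square, x$p_value))
  cat("  observed:", paste(round(x$observed, 2), collapse = ", "),
      " expected:", paste(round(x$expected, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Tertile survival comparison
#'
#' The upper-versus-bottom-third survival protocol: samples are split into
#' score tertiles, the middle tertile is set aside, and the `high` and
#' `low` groups are compared with the log-rank test.
#'
#' @param scores per-sample scores.
#' @param time,event survival records aligned with `scores`.
#' @return list with the tertile `groups` factor, the `logrank` result and
#'   per-group Kaplan-Meier `curves`.
#' @export
survival_tertile_test <- function(scores, time, event) {
  g <- tertile_groups(scores)
  keep <- g %in% c("low", "high") & !is.na(time) & !is.na(event)
  lr <- logrank_test(time[keep], event[keep], droplevels(g[keep]))
  curves <- lapply(c(low = "low", high = "high"), function(lv) {
    i <- keep & g == lv
    kaplan_meier(time[i], event[i])
  })
  list(groups = g, logrank = lr, curves = curves)
}
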