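#' Methylation-based intratumour heterogeneity scoring
#'
#' The score of a tumour sample is the spread, across genes, of its deviation
#' from the cohort mean methylation profile. With per-gene deviations
#' \eqn{\Delta_i = \beta_i - \bar\beta_i} (sample value minus cohort mean) and
#' \eqn{m} genes with non-missing deviations, the default ("printed")
#' estimator is
#' \deqn{\sqrt{\frac{1}{m-1}\sum_i \Delta_i^2 -
#'       \Big(\frac{1}{m}\sum_i \Delta_i\Big)^2}.}
#' It mixes a \eqn{1/(m-1)} sum of squares with the square of a \eqn{1/m}
#' mean and is therefore not exactly the textbook sample standard deviation;
#' the "unbiased" estimator \eqn{\mathrm{sd}(\Delta)} is offered as the
#' orthodox alternative. The radicand of the printed form is mathematically
#' non-negative; if floating point drives it below zero it is clamped to 0.
#'
#' @name myth-score
#' @keywords internal
NULL

#' Per-gene cohort reference means
#'
#' @param x gene-level matrix (genes in rows, samples in columns), at least
#'   2 samples. Missing values are excluded per gene; genes missing in every
#'   sample get a missing mean.
#' @return object of class `myth_reference`: list with `gene_ids`, `means`,
#'   `t` (number of reference samples) and `n_obs` (non-missing count per
#'   gene).
#' @export
reference_means <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("reference cohort needs at least 2 samples")
  n_obs <- rowSums(!is.na(x))
  means <- rowMeans(x, na.rm = TRUE)
  means[n_obs == 0L] <- NA_real_
  structure(list(gene_ids = rownames(x), means = unname(means),
                 t = ncol(x), n_obs = unname(n_obs)),
            class = "myth_reference")
}

#' @export
print.myth_reference <- function(x, ...) {
  cat(sprintf("Cohort reference means: %d gene(s) over t = %d sample(s)\n",
              length(x$gene_ids), x$t))
  invisible(x)
}

#' Per-sample deviation profile from cohort means
#'
#' @param x gene-level matrix containing `sample_id`.
#' @param sample_id column to profile.
#' @param reference a [reference_means()] object.
#' @return object of class `delta_profile`: list with `sample_id`,
#'   `gene_ids`, `delta` (missing wherever the sample value or the reference
#'   mean is missing) and `m_effective`.
#' @export
delta_profile <- function(x, sample_id, reference) {
  x <- as.matrix(x)
  if (!sample_id %in% colnames(x)) stop("unknown sample: ", sample_id)
  common <- intersect(rownames(x), reference$gene_ids)
  if (!length(common)) stop("no genes shared with the reference")
  mu <- reference$means[match(common, reference$gene_ids)]
  delta <- x[common, sample_id] - mu
  structure(list(sample_id = sample_id, gene_ids = common,
                 delta = unname(delta),
                 m_effective = sum(!is.na(delta))),
            class = "delta_profile")
}

#' Heterogeneity score of one deviation profile
#'
#' @param delta a [delta_profile()] object or a numeric vector of deviations
#'   (missing values allowed).
#' @param estimator `"printed"` evaluates the displayed formula literally;
#'   `"unbiased"` is the textbook sample standard deviation. See Details in
#'   the package vignette.
#' @param min_genes minimum number of non-missing deviations (>= 2) required
#'   for a score; below it the score is missing with a warning. The default
#'   of 100 is conservative: a standard deviation over a handful of genes is
#'   noise.
#' @return a non-negative number, or `NA` when fewer than `min_genes`
#'   deviations are available.
#' @export
myth_score <- function(delta, estimator = c("printed", "unbiased"),
                       min_genes = 100L) {
  estimator <- match.arg(estimator)
  if (inherits(delta, "delta_profile")) delta <- delta$delta
  if (min_genes < 2L) stop("min_genes must be >= 2")
  d <- delta[!is.na(delta)]
  m <- length(d)
  if (m < min_genes) {
    warning(sprintf("only %d non-missing deviation(s) (< min_genes = %d); score is NA",
                    m, min_genes))
    return(NA_real_)
  }
  .myth_score_num(d, estimator)
}

# two-pass evaluation: explicit mean first, then centred/squared sums, to
# limit cancellation in the printed formula's subtraction of near-equal terms
.myth_score_num <- function(d, estimator) {
  m <- length(d)
  mu <- sum(d) / m
  if (estimator == "unbiased")
    return(sqrt(sum((d - mu)^2) / (m - 1)))
  rad <- sum(d^2) / (m - 1) - mu * mu
  if (rad < 0) rad <- 0
  sqrt(rad)
}

#' Score a tumour cohort for intratumour heterogeneity
#'
#' The main fitting function. Per-gene cohort means are computed once from
#' all samples of the matrix (the scored sample included -- the reference
#' mean runs over all tumour samples; `reference = "loo"` excludes each
#' scored sample from its own reference instead), every sample's deviation
#' profile is formed against them, and each profile is summarised by the
#' spread estimator.
#'
#' @param x gene-level numeric matrix (genes in rows, samples in columns,
#'   at least 2 samples) such as from [read_beta_matrix()].
#' @inheritParams myth_score
#' @param reference `"pooled"` (default: shared cohort means) or `"loo"`
#'   (leave-one-out means per scored sample).
#' @return an object of class `myth`: list with per-sample `scores`,
#'   `n_genes_used`, the `estimator`, `min_genes`, `reference` policy,
#'   the pooled `ref_means`, `t` and the matched `call`. Methods:
#'   [print()], [summary()], [coef()] (the scores), [predict()] (score new
#'   samples against the stored reference), [plot()], [as.data.frame()].
#' @examples
#' set.seed(1)
#' m <- matrix(runif(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' fit <- myth(m, min_genes = 10)
#' coef(fit)
#' @export
myth <- function(x, estimator = c("printed", "unbiased"), min_genes = 100L,
                 reference = c("pooled", "loo")) {
  estimator <- match.arg(estimator)
  reference <- match.arg(reference)
  x <- as.matrix(x)
  if (min_genes < 2L) stop("min_genes must be >= 2")
  if (ncol(x) < 2L) stop("cohort needs at least 2 samples")
  ref <- reference_means(x)
  t_ <- ncol(x)
  if (reference == "pooled") {
    deltas <- x - ref$means      # recycles per-gene means down columns
  } else {
    # leave-one-out: per gene, drop the scored sample's own value from the mean
    sums <- rowSums(x, na.rm = TRUE)
    cnts <- rowSums(!is.na(x))
    loo_n <- cnts - !is.na(x)
    loo_sum <- sums - ifelse(is.na(x), 0, x)
    loo_mu <- ifelse(loo_n > 0, loo_sum / loo_n, NA_real_)
    deltas <- x - loo_mu
  }
  m_eff <- colSums(!is.na(deltas))
  storage.mode(m_eff) <- "integer"
  scores <- vapply(seq_len(ncol(x)), function(j) {
    d <- deltas[, j]
    d <- d[!is.na(d)]
    if (length(d) < min_genes) NA_real_ else .myth_score_num(d, estimator)
  }, numeric(1L))
  if (anyNA(scores))
    warning(sum(is.na(scores)),
            " sample(s) below min_genes = ", min_genes, "; score set to NA")
  names(scores) <- colnames(x)
  names(m_eff) <- colnames(x)
  structure(list(scores = scores, n_genes_used = m_eff,
                 estimator = estimator, min_genes = as.integer(min_genes),
                 reference = reference, ref_means = ref, t = t_,
                 call = match.call()),
            class = "myth")
}

#' Score external samples against a fixed tumour reference
#'
#' Each external sample (e.g. a normal control) is scored using the tumour
#' cohort's reference means; the reference is never re-centred on the
#' external samples. This is the protocol behind comparing normal controls
#' with tumours on the tumour cohort's own scale.
#'
#' @param external gene-level matrix of external samples.
#' @param reference a [reference_means()] object or a fitted [myth()] object
#'   (its pooled reference means are used).
#' @inheritParams myth_score
#' @return a `myth` object for the external samples.
#' @export
score_against_reference <- function(external, reference,
                                    estimator = c("printed", "unbiased"),
                                    min_genes = 100L) {
  estimator <- match.arg(estimator)
  if (inherits(reference, "myth")) reference <- reference$ref_means
  if (!inherits(reference, "myth_reference"))
    stop("reference must be a myth_reference or myth object")
  external <- as.matrix(external)
  if (min_genes < 2L) stop("min_genes must be >= 2")
  common <- intersect(rownames(external), reference$gene_ids)
  if (!length(common)) stop("no genes shared with the reference")
  mu <- reference$means[match(common, reference$gene_ids)]
  deltas <- external[common, , drop = FALSE] - mu
  m_eff <- colSums(!is.na(deltas))
  storage.mode(m_eff) <- "integer"
  scores <- vapply(seq_len(ncol(deltas)), function(j) {
    d <- deltas[, j]
    d <- d[!is.na(d)]
    if (length(d) < min_genes) NA_real_ else .myth_score_num(d, estimator)
  }, numeric(1L))
  if (anyNA(scores))
    warning(sum(is.na(scores)),
            " sample(s) below min_genes = ", min_genes, "; score set to NA")
  names(scores) <- colnames(external)
  names(m_eff) <- colnames(external)
  structure(list(scores = scores, n_genes_used = m_eff,
                 estimator = estimator, min_genes = as.integer(min_genes),
                 reference = "external", ref_means = reference,
                 t = reference$t, call = match.call()),
            class = "myth")
}

#' @export
print.myth <- function(x, ...) {
  cat("Methylation heterogeneity scores\n")
  cat(sprintf("  %d sample(s), estimator = %s, reference = %s (t = %d)\n",
              length(x$scores), x$estimator, x$reference, x$t))
  print(utils::head(round(x$scores, 6), 10L))
  if (length(x$scores) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
summary.myth <- function(object, ...) {
  s <- object$scores
  out <- list(n = length(s), n_missing = sum(is.na(s)),
              estimator = object$estimator, reference = object$reference,
              t = object$t, min_genes = object$min_genes,
              quantiles = stats::quantile(s, na.rm = TRUE),
              genes_used = range(object$n_genes_used))
  class(out) <- "summary.myth"
  out
}

#' @export
print.summary.myth <- function(x, ...) {
  cat("Methylation heterogeneity score summary\n")
  cat(sprintf("  samples: %d (%d unscored), estimator: %s, reference: %s, t = %d\n",
              x$n, x$n_missing, x$estimator, x$reference, x$t))
  cat(sprintf("  genes used per sample: %d-%d (min_genes = %d)\n",
              x$genes_used[1L], x$genes_used[2L], x$min_genes))
  print(round(x$quantiles, 6))
  invisible(x)
}

#' @export
coef.myth <- function(object, ...) object$scores

#' @export
as.data.frame.myth <- function(x, ...) {
  data.frame(sample_id = names(x$scores), myth_score = unname(x$scores),
             n_genes_used = unname(x$n_genes_used),
             stringsAsFactors = FALSE)
}

#' @param object a fitted `myth` object.
#' @param newdata gene-level matrix of new samples to score against the
#'   fit's stored pooled reference means.
#' @rdname myth
#' @export
predict.myth <- function(object, newdata, ...) {
  score_against_reference(newdata, object$ref_means,
                          estimator = object$estimator,
                          min_genes = object$min_genes)
}

#' @export
plot.myth <- function(x, breaks = 30, main = "Heterogeneity scores",
                      xlab = "score", ...) {
  graphics::hist(x$scores, breaks = breaks, main = main, xlab = xlab, ...)
  invisible(x)
}
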