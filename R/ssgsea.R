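#' Single-sample gene set enrichment (ssGSEA)
#'
#' Rank-based running-sum statistic for the coordinate up/down shift of a
#' gene set within one sample's profile. Genes are ranked by value
#' (descending; rank weights give the highest value the largest weight,
#' ties by average rank). Walking the ranked list, in-set genes accumulate
#' weight^alpha normalised by the total in-set weight and out-of-set genes
#' accumulate 1/(N - |set|); the enrichment score is the sum over all list
#' positions of the running difference (the integrated difference that
#' distinguishes ssGSEA from classic GSEA's maximum deviation). `alpha = 0`
#' gives the unweighted Kolmogorov-Smirnov-style running sum.
#'
#' @param values per-gene numeric values of one sample (no missing values;
#'   the caller imputes or drops beforehand).
#' @param genes gene identifiers aligned with `values` (defaults to
#'   `names(values)`).
#' @param set_members gene identifiers of the set; at least one must be
#'   present among `genes`.
#' @param alpha non-negative rank-weight exponent; 0.25 is the common
#'   ssGSEA default.
#' @return the enrichment score (a single number).
#' @export
ssgsea_sample <- function(values, genes = names(values), set_members,
                          alpha = 0.25) {
  if (is.null(genes)) stop("gene identifiers required")
  n <- length(values)
  if (n < 2L) stop("need at least 2 genes")
  if (anyNA(values)) stop("missing values in profile; impute or drop first")
  if (alpha < 0) stop("alpha must be non-negative")
  in_set_gene <- genes %in% set_members
  n_in <- sum(in_set_gene)
  if (n_in == 0L)
    stop("no member of the gene set is present in the profile")
  if (length(unique(values)) == 1L)
    stop("all values identical; ranking undefined")
  # weights: average rank, largest value -> largest weight; list position:
  # value-descending, ties kept in stable input order
  w <- rank(values, ties.method = "average")^alpha
  ord <- order(-values)
  in_set <- in_set_gene[ord]
  step_in <- ifelse(in_set, w[ord], 0)
  cum_in <- cumsum(step_in) / sum(w[in_set_gene])
  n_out <- n - n_in
  cum_out <- if (n_out > 0L) cumsum(!in_set) / n_out else rep(0, n)
  sum(cum_in - cum_out)
}

#' ssGSEA scores for a gene set collection over a cohort
#'
#' Rows (genes) with any missing value are dropped with a warning before
#' ranking. Sets with no member present score `NA` with a warning when at
#' least one other set succeeds; if no set has any member present the call
#' errors. With `normalize = TRUE` every raw score is divided by the range
#' (max - min) of all sets' and samples' raw scores pooled, the conventional
#' normalised enrichment score.
#'
#' The ranking quantity is whatever the matrix holds -- methylation beta
#' values and expression values are treated identically.
#'
#' @param x gene-by-sample numeric matrix.
#' @param sets a [read_gmt()] collection, or a named list of gene
#'   identifier vectors.
#' @param alpha rank-weight exponent, see [ssgsea_sample()].
#' @param normalize divide by the pooled score range (default off).
#' @return object of class `enrichment_matrix`: signatures-by-samples
#'   numeric matrix with attributes `alpha` and `normalized`.
#' @export
ssgsea <- function(x, sets, alpha = 0.25, normalize = FALSE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("matrix requires gene row names")
  if (!is.list(sets)) stop("sets must be a list of gene identifier vectors")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning(sum(!keep), " gene row(s) with missing values dropped")
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("fewer than 2 complete gene rows")
  genes <- rownames(x)
  present <- vapply(sets, function(s) any(s %in% genes), logical(1L))
  if (!any(present))
    stop("no gene set has any member present in the matrix")
  if (!all(present))
    warning("gene set(s) with no member present scored NA: ",
            paste(names(sets)[!present], collapse = ", "))
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    for (k in which(present))
      scores[k, j] <- ssgsea_sample(v, genes, sets[[k]], alpha)
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    span <- rng[2L] - rng[1L]
    if (span > 0) scores <- scores / span
  }
  structure(scores, alpha = alpha, normalized = isTRUE(normalize),
            class = c("enrichment_matrix", class(scores)))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("ssGSEA enrichment: %d signature(s) x %d sample(s), alpha = %g%s\n",
              nrow(x), ncol(x), attr(x, "alpha"),
              if (isTRUE(attr(x, "normalized"))) ", normalised" else ""))
  print(utils::head(round(unclass(x), 4), c(5L, 5L)))
  invisible(x)
}
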