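# Independent oracles and fixture builders. Everything here is a literal,
# unoptimised re-derivation from first principles, kept deliberately apart
# from the package's code paths.

rand_beta_matrix <- function(n_genes, n_samples, missing_frac = 0) {
  m <- matrix(runif(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (missing_frac > 0) {
    idx <- which(runif(length(m)) < missing_frac)
    m[idx] <- NA_real_
  }
  m
}

# literal evaluation of the displayed score: per gene the cohort mean over
# non-missing values, per sample the deviations, then
# sqrt( sum(d^2)/(m-1) - (sum(d)/m)^2 ), all with plain loops
naive_myth_scores <- function(mat, estimator = "printed") {
  nG <- nrow(mat); nS <- ncol(mat)
  mu <- numeric(nG)
  for (i in seq_len(nG)) {
    v <- mat[i, ]
    v <- v[!is.na(v)]
    mu[i] <- if (length(v)) sum(v) / length(v) else NA_real_
  }
  scores <- numeric(nS)
  for (j in seq_len(nS)) {
    d <- c()
    for (i in seq_len(nG)) {
      if (!is.na(mat[i, j]) && !is.na(mu[i]))
        d <- c(d, mat[i, j] - mu[i])
    }
    m <- length(d)
    if (m < 2) { scores[j] <- NA_real_; next }
    if (estimator == "printed") {
      rad <- sum(d^2) / (m - 1) - (sum(d) / m)^2
      scores[j] <- sqrt(max(rad, 0))
    } else {
      mn <- sum(d) / m
      scores[j] <- sqrt(sum((d - mn)^2) / (m - 1))
    }
  }
  names(scores) <- colnames(mat)
  scores
}

# exact Mann-Whitney p by full enumeration of which pooled positions belong
# to group a (all C(n1+n2, n1) assignments equally likely under the null)
enumerate_mw_p <- function(a, b, alternative) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_null <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (alternative == "greater") mean(u_null >= u_obs) else mean(u_null <= u_obs)
}

# literal position-by-position ssGSEA walk
walk_ssgsea <- function(values, genes, set_members, alpha) {
  n <- length(values)
  w <- rank(values, ties.method = "average")^alpha
  ord <- order(-values)
  n_in <- sum(genes %in% set_members)
  denom_in <- sum(w[genes %in% set_members])
  cum_in <- 0; cum_out <- 0; es <- 0
  for (pos in seq_len(n)) {
    g <- ord[pos]
    if (genes[g] %in% set_members) cum_in <- cum_in + unname(w[g]) / denom_in
    else cum_out <- cum_out + 1 / (n - n_in)
    es <- es + (cum_in - cum_out)
  }
  unname(es)
}

# tie-aware ranks by counting, then the Pearson formula by loops
brute_spearman_rho <- function(x, y) {
  n <- length(x)
  rk <- function(v) vapply(seq_len(n), function(i)
    (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my_ <- mean(ry)
  sum((rx - mx) * (ry - my_)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my_)^2))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
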