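# frozen from the oracle: sqrt((1/2)(0.01 + 0.04 + 0.09) - ((0.1 - 0.2 + 0.3)/3)^2)
DELTA_FIXTURE_SCORE <- 0.2560381915956203

test_that("cohort reference means are missing-aware and need >= 2 samples", {
  m <- matrix(c(0.2, 0.5, NA,
                0.4, NA, NA),
              nrow = 3, ncol = 2,
              dimnames = list(c("gA", "gB", "gC"), c("S1", "S2")))
  ref <- reference_means(m)
  expect_equal(ref$means, c(0.3, 0.5, NA))
  expect_equal(ref$n_obs, c(2L, 1L, 0L))
  expect_identical(ref$t, 2L)
  expect_error(reference_means(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("delta profiles subtract reference means and propagate missingness", {
  m <- matrix(c(0.7, NA, 0.3,
                0.1, 0.6, 0.3),
              nrow = 3, ncol = 2,
              dimnames = list(c("gA", "gB", "gC"), c("S1", "S2")))
  ref <- reference_means(m)
  d <- delta_profile(m, "S1", ref)
  expect_equal(d$delta, c(0.7 - 0.4, NA, 0))
  expect_identical(d$m_effective, 2L)
  expect_error(delta_profile(m, "nope", ref), "unknown sample")

  # a sample equal to the reference means has an all-zero profile
  m2 <- cbind(m, S3 = ref$means)
  ref2 <- reference_means(m[, 1:2])
  d3 <- delta_profile(m2, "S3", ref2)
  expect_true(all(d3$delta == 0, na.rm = TRUE))
})

test_that("myth_score matches the frozen oracle value and algebraic cases", {
  # constant deltas: unbiased gives 0, printed gives |d| * sqrt(1/(m-1))
  for (m_ in c(3L, 7L, 50L)) {
    d <- rep(0.25, m_)
    expect_equal(myth_score(d, "unbiased", min_genes = 2), 0)
    expect_equal(myth_score(d, "printed", min_genes = 2),
                 0.25 * sqrt(1 / (m_ - 1)))
  }
  expect_equal(myth_score(rep(0, 10), "printed", min_genes = 2), 0)
  expect_equal(myth_score(rep(0, 10), "unbiased", min_genes = 2), 0)

  expect_equal(myth_score(c(0.1, -0.2, 0.3), "printed", min_genes = 2),
               DELTA_FIXTURE_SCORE, tolerance = 1e-15)

  # missing deltas are excluded from m
  expect_equal(myth_score(c(0.1, NA, -0.2, 0.3, NA), "printed", min_genes = 2),
               DELTA_FIXTURE_SCORE, tolerance = 1e-15)

  expect_warning(s <- myth_score(c(0.1, -0.2, 0.3), min_genes = 100),
                 "min_genes")
  expect_true(is.na(s))
  expect_error(myth_score(c(0.1, 0.2), min_genes = 1), "min_genes must be >= 2")
})

test_that("score_cohort equals the literal two-pass oracle on random data", {
  set.seed(101)
  for (rep_ in 1:10) {
    m <- rand_beta_matrix(sample(5:60, 1), sample(3:12, 1),
                          missing_frac = sample(c(0, 0.1), 1))
    fit <- suppressWarnings(myth(m, min_genes = 2))
    expect_equal(coef(fit), naive_myth_scores(m, "printed"),
                 tolerance = 1e-12)
    fitu <- suppressWarnings(myth(m, estimator = "unbiased", min_genes = 2))
    expect_equal(coef(fitu), naive_myth_scores(m, "unbiased"),
                 tolerance = 1e-12)
  }
})

test_that("degenerate cohorts score zero", {
  m <- matrix(0.42, 25, 6,
              dimnames = list(paste0("g", 1:25), paste0("s", 1:6)))
  expect_true(all(coef(myth(m, min_genes = 2)) == 0))
  # one sample equal to the per-gene cohort mean scores exactly 0
  set.seed(5)
  base <- rand_beta_matrix(40, 5)
  # append col6 = rowMeans(base): then the 6-sample cohort mean equals col6
  m2 <- cbind(base, s_mean = rowMeans(base))
  fit <- myth(m2, min_genes = 2)
  expect_equal(unname(coef(fit)["s_mean"]), 0)
})

test_that("leave-one-out reference excludes the scored sample from its mean", {
  set.seed(11)
  m <- rand_beta_matrix(30, 4)
  fit <- myth(m, min_genes = 2, reference = "loo")
  # manual check for sample 2
  mu_loo <- rowMeans(m[, -2])
  d <- m[, 2] - mu_loo
  expected <- sqrt(sum(d^2) / (length(d) - 1) - (sum(d) / length(d))^2)
  expect_equal(unname(coef(fit)[2]), expected, tolerance = 1e-12)
  # pooled and loo differ on non-degenerate data
  expect_false(isTRUE(all.equal(coef(fit), coef(myth(m, min_genes = 2)))))
})

test_that("external samples are scored against a fixed reference", {
  set.seed(23)
  cohort <- rand_beta_matrix(50, 8)
  fit <- myth(cohort, min_genes = 2)
  # identical matrix scored externally reproduces the cohort scores
  ext <- score_against_reference(cohort, fit, min_genes = 2)
  expect_equal(coef(ext), coef(fit), tolerance = 1e-15)
  # a sample equal to the reference means scores 0
  mu <- matrix(fit$ref_means$means, ncol = 1,
               dimnames = list(fit$ref_means$gene_ids, "ctrl"))
  expect_equal(unname(coef(score_against_reference(mu, fit, min_genes = 2))), 0)
  # predict() is the same protocol
  expect_equal(coef(predict(fit, cohort)), coef(fit), tolerance = 1e-15)
  expect_error(score_against_reference(
    matrix(0.5, 2, 2, dimnames = list(c("x1", "x2"), c("a", "b"))),
    fit, min_genes = 2), "no genes shared")
})

test_that("scores obey offset, scaling and permutation invariances", {
  set.seed(31)
  m <- rand_beta_matrix(60, 7)
  base_p <- coef(myth(m, min_genes = 2))
  base_u <- coef(myth(m, estimator = "unbiased", min_genes = 2))

  # per-gene offsets across all samples cancel in every delta
  offs <- m + rnorm(nrow(m))  # recycled down columns = per-gene constant
  expect_equal(coef(myth(offs, min_genes = 2)), base_p, tolerance = 1e-12)
  expect_equal(coef(myth(offs, estimator = "unbiased", min_genes = 2)),
               base_u, tolerance = 1e-12)

  # positive homogeneity
  k <- 3.7
  expect_equal(coef(myth(k * m, min_genes = 2)), k * base_p,
               tolerance = 1e-12)
  expect_equal(coef(myth(k * m, estimator = "unbiased", min_genes = 2)),
               k * base_u, tolerance = 1e-12)

  # gene- and sample-order permutation invariance
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  expect_equal(coef(myth(perm, min_genes = 2))[names(base_p)], base_p,
               tolerance = 1e-12)

  # per-sample constant offset leaves the unbiased score unchanged
  m2 <- m
  m2[, 3] <- m2[, 3] + 0.2
  expect_equal(coef(myth(m2, estimator = "unbiased", min_genes = 2))[3],
               base_u[3], tolerance = 1e-10)

  expect_true(all(base_p >= 0) && all(base_u >= 0))
})

test_that("samples below min_genes get NA scores with a warning", {
  set.seed(41)
  m <- rand_beta_matrix(20, 3)
  m[6:20, 2] <- NA  # sample 2 has 5 usable genes
  expect_warning(fit <- myth(m, min_genes = 10), "below min_genes")
  expect_true(is.na(coef(fit)[2]))
  expect_false(anyNA(coef(fit)[-2]))
  expect_identical(unname(fit$n_genes_used[2]), 5L)
})

test_that("myth object methods expose scores coherently", {
  set.seed(51)
  m <- rand_beta_matrix(30, 5)
  fit <- myth(m, min_genes = 2)
  df <- as.data.frame(fit)
  expect_equal(df$sample_id, colnames(m))
  expect_equal(df$myth_score, unname(coef(fit)))
  s <- summary(fit)
  expect_identical(s$n, 5L)
  expect_output(print(fit), "estimator = printed")
  expect_output(print(s), "samples: 5")
})
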