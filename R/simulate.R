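#' Clonal-mixture methylation cohort simulator
#'
#' Generates a synthetic tumour cohort of beta-value profiles with known
#' per-sample clonal divergence and purity, so the scoring and association
#' machinery can be validated without external downloads. The generative
#' model, in draw order (all randomness from R's Mersenne-Twister stream,
#' seeded once -- the draw order is part of the contract so fixtures stay
#' stable):
#'
#' 1. a consensus beta profile per gene from a symmetric Beta(c, c)
#'    distribution (the concentration c controls its spread; the default
#'    0.5 gives the bimodal, U-shaped genome-wide beta distribution typical
#'    of methylation arrays);
#' 2. per sample: a divergence level (uniform over `divergence` when a
#'    range, constant when scalar), a clone count K uniform over
#'    `n_clones_range`, flat-Dirichlet mixing weights, a purity uniform
#'    over `purity_range`, then K clone profiles obtained by perturbing the
#'    consensus on the logit scale with independent Gaussian deviations of
#'    SD = divergence;
#' 3. the bulk profile = purity x (weighted mixture of clone betas) +
#'    (1 - purity) x consensus (the non-tumour fraction carries the
#'    consensus, "stromal", profile), plus logit-scale Gaussian measurement
#'    noise of SD `noise_sd`, squashed back into [0, 1];
#' 4. optional normal controls: consensus plus measurement noise only
#'    (divergence 0).
#'
#' The recorded ground truth per sample is the *realized* divergence: the
#' mixture-weighted mean absolute logit-scale deviation of its clones from
#' the consensus. With a finite gene panel the realized value, not the
#' nominal SD parameter, is the unbiased yardstick for recovery tests.
#'
#' @param n_genes number of genes (>= 10); default 2000.
#' @param n_samples number of tumour samples (>= 4); default 200.
#' @param n_clones_range integer interval for the per-sample clone count;
#'   default 2 to 5 subclones, a typical bulk-tumour range.
#' @param divergence scalar (constant across samples) or length-2 range
#'   (per-sample uniform) for the clone-deviation SD on the logit scale;
#'   default `c(0.1, 1.5)`, spanning near-homogeneous to strongly divergent
#'   tumours.
#' @param purity_range interval within [0, 1] for tumour purity; default
#'   `c(0.5, 0.95)`, the usual bulk-tumour purity band.
#' @param noise_sd logit-scale measurement noise SD; default 0.1.
#' @param concentration symmetric Beta concentration of the consensus
#'   profile; default 0.5.
#' @param n_normals number of normal-control samples (default 0).
#' @param seed integer seed (mandatory; the cohort is fully reproducible
#'   from it).
#' @return object of class `simulated_cohort`: list with `beta`
#'   (gene-by-sample matrix in [0, 1]), `truth` (data.frame: `sample_id`,
#'   `n_clones`, `purity`, `divergence_nominal`, `divergence` = realized),
#'   `normals` (matrix or NULL), `consensus`, `survival` (NULL until
#'   [attach_survival()]), and the `config`.
#' @export
simulate_cohort <- function(n_genes = 2000L, n_samples = 200L,
                            n_clones_range = c(2L, 5L),
                            divergence = c(0.1, 1.5),
                            purity_range = c(0.5, 0.95),
                            noise_sd = 0.1, concentration = 0.5,
                            n_normals = 0L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genes < 10L) stop("n_genes must be >= 10")
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (length(n_clones_range) != 2L || diff(n_clones_range) < 0 ||
      n_clones_range[1L] < 1L)
    stop("invalid n_clones_range")
  if (!length(divergence) %in% c(1L, 2L) || any(divergence < 0) ||
      (length(divergence) == 2L && diff(divergence) < 0))
    stop("invalid divergence")
  if (length(purity_range) != 2L || diff(purity_range) < 0 ||
      purity_range[1L] < 0 || purity_range[2L] > 1)
    stop("invalid purity_range")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (concentration <= 0) stop("concentration must be positive")

  .with_seed(seed, {
    consensus <- stats::rbeta(n_genes, concentration, concentration)
    lcons <- stats::qlogis(.squeeze(consensus))
    beta <- matrix(NA_real_, n_genes, n_samples)
    truth <- data.frame(sample_id = sprintf("T%03d", seq_len(n_samples)),
                        n_clones = NA_integer_, purity = NA_real_,
                        divergence_nominal = NA_real_,
                        divergence = NA_real_,
                        stringsAsFactors = FALSE)
    for (s in seq_len(n_samples)) {
      div_s <- if (length(divergence) == 2L)
        stats::runif(1L, divergence[1L], divergence[2L]) else divergence
      k <- if (n_clones_range[1L] == n_clones_range[2L]) n_clones_range[1L]
           else sample(seq.int(n_clones_range[1L], n_clones_range[2L]), 1L)
      w <- stats::rgamma(k, shape = 1)      # flat Dirichlet
      w <- w / sum(w)
      purity <- stats::runif(1L, purity_range[1L], purity_range[2L])
      if (div_s > 0) {
        eps <- matrix(stats::rnorm(n_genes * k, sd = div_s), n_genes, k)
        clones <- stats::plogis(lcons + eps)
        mix <- drop(clones %*% w)
        realized <- sum(w * colMeans(abs(eps)))
        bulk <- purity * mix + (1 - purity) * consensus
      } else {
        realized <- 0
        bulk <- consensus   # mixing identical profiles is the identity
      }
      if (noise_sd > 0)
        bulk <- stats::plogis(stats::qlogis(.squeeze(bulk)) +
                                stats::rnorm(n_genes, sd = noise_sd))
      beta[, s] <- bulk
      truth$n_clones[s] <- k
      truth$purity[s] <- purity
      truth$divergence_nominal[s] <- div_s
      truth$divergence[s] <- realized
    }
    dimnames(beta) <- list(sprintf("g%05d", seq_len(n_genes)),
                           truth$sample_id)
    normals <- NULL
    if (n_normals > 0L) {
      normals <- matrix(NA_real_, n_genes, n_normals)
      for (s in seq_len(n_normals)) {
        normals[, s] <- if (noise_sd > 0)
          stats::plogis(lcons + stats::rnorm(n_genes, sd = noise_sd))
        else consensus
      }
      dimnames(normals) <- list(rownames(beta),
                                sprintf("N%03d", seq_len(n_normals)))
    }
    structure(list(beta = beta, truth = truth, normals = normals,
                   consensus = stats::setNames(consensus, rownames(beta)),
                   survival = NULL,
                   config = list(n_genes = n_genes, n_samples = n_samples,
                                 n_clones_range = n_clones_range,
                                 divergence = divergence,
                                 purity_range = purity_range,
                                 noise_sd = noise_sd,
                                 concentration = concentration,
                                 n_normals = n_normals, seed = seed)),
              class = "simulated_cohort")
  })
}

# run expr under a given seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# keep strictly inside (0,1) so qlogis stays finite
.squeeze <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated methylation cohort: %d gene(s) x %d tumour sample(s)",
              nrow(x$beta), ncol(x$beta)))
  if (!is.null(x$normals)) cat(sprintf(" + %d normal(s)", ncol(x$normals)))
  cat(sprintf("\n  divergence (realized): %.3f-%.3f; purity: %.2f-%.2f; seed %d\n",
              min(x$truth$divergence), max(x$truth$divergence),
              min(x$truth$purity), max(x$truth$purity), x$config$seed))
  if (!is.null(x$survival))
    cat(sprintf("  survival attached: %d event(s) / %d sample(s)\n",
                sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Attach proportional-hazards survival records to a simulated cohort
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(log_hazard_per_divergence * divergence)`, where
#' divergence is the realized ground truth. Censoring times are independent
#' exponentials with the rate tuned so each sample's expected probability
#' of being censored first equals `censor_rate`; `censor_rate = 0` produces
#' no censoring.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param baseline_hazard positive baseline event rate.
#' @param log_hazard_per_divergence log hazard ratio per unit realized
#'   divergence (0 = survival unlinked to heterogeneity).
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed integer seed for the survival draws.
#' @return the cohort with a `survival` data.frame (`sample_id`, `time`,
#'   `event`).
#' @export
attach_survival <- function(cohort, baseline_hazard = 0.1,
                            log_hazard_per_divergence = 0,
                            censor_rate = 0.2, seed) {
  if (!inherits(cohort, "simulated_cohort")) stop("not a simulated cohort")
  if (missing(seed)) stop("seed is mandatory")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  n <- nrow(cohort$truth)
  .with_seed(seed, {
    hz <- baseline_hazard * exp(log_hazard_per_divergence *
                                  cohort$truth$divergence)
    t_event <- stats::rexp(n, rate = hz)
    if (censor_rate > 0) {
      c_rate <- hz * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    cohort$survival <- data.frame(sample_id = cohort$truth$sample_id,
                                  time = pmin(t_event, t_cens),
                                  event = as.integer(t_event <= t_cens),
                                  stringsAsFactors = FALSE)
    cohort
  })
}

#' Embed a divergence-linked gene signature into a simulated cohort
#'
#' Shifts the member genes of each sample on the logit scale by
#' `effect_per_divergence * realized divergence`, creating ground truth for
#' signature-versus-heterogeneity correlation tests: a positive effect
#' implies an expected positive Spearman correlation between the
#' heterogeneity score and the set's ssGSEA score, a negative effect the
#' mirror image.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param set_members gene identifiers, all present in the cohort.
#' @param effect_per_divergence logit-scale shift per unit realized
#'   divergence.
#' @return the cohort with modified member-gene values.
#' @export
embed_signature <- function(cohort, set_members, effect_per_divergence) {
  if (!inherits(cohort, "simulated_cohort")) stop("not a simulated cohort")
  missing_g <- setdiff(set_members, rownames(cohort$beta))
  if (length(missing_g))
    stop("unknown gene(s): ", paste(utils::head(missing_g, 5L), collapse = ", "))
  if (effect_per_divergence == 0) return(cohort)
  shift <- effect_per_divergence * cohort$truth$divergence
  sub <- cohort$beta[set_members, , drop = FALSE]
  cohort$beta[set_members, ] <-
    stats::plogis(sweep(stats::qlogis(.squeeze(sub)), 2L, shift, "+"))
  cohort
}
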