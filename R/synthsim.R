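# Synthetic two-sample GWAS summary statistics with attached ground truth,
# plus block-structured LD panels, for end-to-end validation of the MR
# pipeline without external downloads.

# Deterministic per-stage sub-seed derived from one base seed, so each
# generation stage draws from its own reproducible stream (kept below 2^31).
split_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 1664525) %% 2147483629
}

#' Ground truth for a synthetic MR dataset
#'
#' Describes the generating model of a synthetic study pair: the true causal
#' effect(s), the pleiotropy mechanism, sample sizes, instrument count, and
#' variance explained. Defaults emulate a univariable analysis of a binary
#' exposure measured in 659,316 individuals (62,892 cases) on a binary
#' outcome measured in 256,896 individuals (29,508 cases), with 128
#' instruments explaining 13.9% of exposure variance and a true log odds
#' ratio of ln(1.069).
#'
#' @param theta true causal effect(s) on the log-odds scale; length 1 for a
#'   univariable scenario, length 2 for the two-exposure scenario.
#' @param n_snps number of instruments; default 128.
#' @param r2_target total exposure variance explained by the instruments, one
#'   value per exposure; default 0.139.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects),
#'   `"directional"` (mean `pleiotropy_mean`), or `"outlier"` (large offsets
#'   at `outlier_indices`).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of per-variant direct
#'   effects for the balanced/directional modes.
#' @param outlier_indices,outlier_offsets planted outlier positions and their
#'   offsets in units of the variant's outcome SE.
#' @param exposure_correlation correlation between the two exposures' true
#'   per-variant effects (two-exposure scenario only); default 0.4.
#' @param n_exposure exposure-study sample size(s), one per exposure.
#' @param n_outcome outcome-study sample size.
#' @param seed base RNG seed; every stage derives its own sub-stream from it.
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(theta = log(1.069), n_snps = 128,
                             r2_target = 0.139,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional", "outlier"),
                             pleiotropy_mean = 0, pleiotropy_sd = 0,
                             outlier_indices = integer(0),
                             outlier_offsets = numeric(0),
                             exposure_correlation = 0.4,
                             n_exposure = 659316, n_outcome = 256896,
                             seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  k <- length(theta)
  stopifnot(k %in% c(1L, 2L), n_snps >= 1,
            all(r2_target >= 0), all(r2_target < 1),
            length(outlier_indices) == length(outlier_offsets),
            all(outlier_indices >= 1), all(outlier_indices <= n_snps),
            abs(exposure_correlation) < 1, all(n_exposure > 1), n_outcome > 1)
  if (length(r2_target) == 1L && k == 2L) r2_target <- rep(r2_target, 2L)
  if (length(n_exposure) == 1L && k == 2L) n_exposure <- rep(n_exposure, 2L)
  stopifnot(length(r2_target) == k, length(n_exposure) == k)
  structure(list(theta = theta, n_snps = as.integer(n_snps),
                 r2_target = r2_target, pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 outlier_indices = as.integer(outlier_indices),
                 outlier_offsets = outlier_offsets,
                 exposure_correlation = exposure_correlation,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# Shared scaffold: rsids, coordinates (each variant on its own locus, >1 Mb
# apart so clumping at a 1,000-kb window never merges them), non-palindromic
# alleles, and uniform allele frequencies.
sim_scaffold <- function(truth) {
  j <- truth$n_snps
  idx <- seq_len(j)
  eaf <- with_local_seed(split_seed(truth$seed, 1L),
                         function() stats::runif(j, 0.05, 0.95))
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- with_local_seed(split_seed(truth$seed, 2L),
                          function() sample.int(4L, j, replace = TRUE))
  list(rsid = sprintf("rs%07d", idx),
       chrom = as.character(((idx - 1L) %% 22L) + 1L),
       pos = 1e6 + ((idx - 1L) %/% 22L) * 5e6,
       effect_allele = pairs[pick, 1L], other_allele = pairs[pick, 2L],
       eaf = eaf)
}

# GWAS-standard SE approximation for a unit-variance trait:
# se ~ 1 / sqrt(2 n p (1 - p)).
se_from_eaf <- function(eaf, n) 1 / sqrt(2 * n * eaf * (1 - eaf))

# Per-variant direct (pleiotropic) outcome effects.
pleiotropy_effects <- function(truth, j, se_y, stage_seed) {
  alpha <- rep(0, j)
  if (truth$pleiotropy_mode %in% c("balanced", "directional")) {
    mu <- if (truth$pleiotropy_mode == "balanced") 0 else truth$pleiotropy_mean
    alpha <- with_local_seed(stage_seed, function() {
      stats::rnorm(j, mu, truth$pleiotropy_sd)
    })
  } else if (truth$pleiotropy_mode == "outlier") {
    alpha[truth$outlier_indices] <-
      truth$outlier_offsets * se_y[truth$outlier_indices]
  }
  alpha
}

sim_stats_df <- function(sc, beta, se, n) {
  data.frame(rsid = sc$rsid, chrom = sc$chrom, pos = sc$pos,
             effect_allele = sc$effect_allele, other_allele = sc$other_allele,
             eaf = sc$eaf, beta = beta, se = se,
             pvalue = pmax(2 * stats::pnorm(-abs(beta / se)),
                           .Machine$double.xmin),
             n = n, stringsAsFactors = FALSE)
}

identity_panel <- function(sc) {
  ld_panel(sc$rsid, diag(1, length(sc$rsid)), sc$chrom, sc$pos)
}

#' Simulate a univariable two-sample study pair
#'
#' Generates exposure and outcome summary statistics for `n_snps` independent
#' instruments under the linear structural model: true exposure effects are
#' drawn with uniform per-variant variance-explained contributions (between
#' 0.25x and 1.75x the mean, emulating an already-selected instrument set in
#' which every variant clears genome-wide significance) and scaled so the
#' total variance explained equals `r2_target`; true outcome effects are
#' `theta * beta_x` plus a pleiotropy term; observed effects add independent
#' sampling noise in the two (non-overlapping) samples, with SEs from the
#' standard `1 / sqrt(2 n p (1 - p))` approximation.
#'
#' @param truth a [simulation_truth()] with a single `theta`.
#' @return An object of class `synthetic_study_pair`: list with
#'   `exposure_stats`, `outcome_stats` (both `gwas_sumstats`), `panel` (an
#'   identity [ld_panel()]: instruments are mutually independent), `truth`,
#'   and the latent `beta_x_true`/`gamma_true`/`alpha` vectors.
#' @export
simulate_univariable <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"), length(truth$theta) == 1L)
  j <- truth$n_snps
  sc <- sim_scaffold(truth)
  u <- with_local_seed(split_seed(truth$seed, 3L),
                       function() stats::runif(j, 0.25, 1.75))
  var_term <- 2 * sc$eaf * (1 - sc$eaf)
  r2_per <- truth$r2_target * u / sum(u)
  # effect alleles are reported aligned to the exposure-increasing direction
  # (the usual convention for instrument tables), so all true exposure
  # effects are positive and the Egger orientation is the generating frame
  beta_x_true <- sqrt(r2_per / var_term)
  se_x <- se_from_eaf(sc$eaf, truth$n_exposure)
  se_y <- se_from_eaf(sc$eaf, truth$n_outcome)
  alpha <- pleiotropy_effects(truth, j, se_y, split_seed(truth$seed, 4L))
  gamma_true <- truth$theta * beta_x_true + alpha
  beta_x_hat <- with_local_seed(split_seed(truth$seed, 5L),
                                function() stats::rnorm(j, beta_x_true, se_x))
  beta_y_hat <- with_local_seed(split_seed(truth$seed, 6L),
                                function() stats::rnorm(j, gamma_true, se_y))
  structure(list(
    exposure_stats = gwas_sumstats(
      sim_stats_df(sc, beta_x_hat, se_x, truth$n_exposure),
      trait = "exposure", sample_n = truth$n_exposure),
    outcome_stats = gwas_sumstats(
      sim_stats_df(sc, beta_y_hat, se_y, truth$n_outcome),
      trait = "outcome", sample_n = truth$n_outcome),
    panel = identity_panel(sc),
    truth = truth,
    beta_x_true = beta_x_true, gamma_true = gamma_true, alpha = alpha
  ), class = "synthetic_study_pair")
}

#' Simulate a two-exposure study triplet for multivariable MR
#'
#' As [simulate_univariable()] but with two correlated exposures: true
#' per-variant effects are drawn from a bivariate normal with correlation
#' `exposure_correlation`, each column scaled to its `r2_target`; the true
#' outcome effect is `theta_1 * beta_x1 + theta_2 * beta_x2` plus pleiotropy.
#' Each exposure is measured in its own sample.
#'
#' @param truth a [simulation_truth()] with `theta` of length 2.
#' @return a `synthetic_study_pair` with an extra `second_exposure_stats`
#'   element and a `beta_x_true` J x 2 matrix.
#' @export
simulate_mvmr <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"), length(truth$theta) == 2L)
  j <- truth$n_snps
  rho <- truth$exposure_correlation
  sc <- sim_scaffold(truth)
  g <- with_local_seed(split_seed(truth$seed, 3L), function() {
    g1 <- stats::rnorm(j)
    g2 <- rho * g1 + sqrt(1 - rho^2) * stats::rnorm(j)
    cbind(g1, g2)
  })
  var_term <- 2 * sc$eaf * (1 - sc$eaf)
  beta_x_true <- vapply(1:2, function(k) {
    scale <- sqrt(truth$r2_target[k] / sum(var_term * g[, k]^2))
    g[, k] * scale
  }, numeric(j))
  se_x <- vapply(1:2, function(k) se_from_eaf(sc$eaf, truth$n_exposure[k]),
                 numeric(j))
  se_y <- se_from_eaf(sc$eaf, truth$n_outcome)
  alpha <- pleiotropy_effects(truth, j, se_y, split_seed(truth$seed, 4L))
  gamma_true <- drop(beta_x_true %*% truth$theta) + alpha
  beta_x_hat <- with_local_seed(split_seed(truth$seed, 5L), function() {
    beta_x_true + matrix(stats::rnorm(2 * j), ncol = 2) * se_x
  })
  beta_y_hat <- with_local_seed(split_seed(truth$seed, 6L),
                                function() stats::rnorm(j, gamma_true, se_y))
  structure(list(
    exposure_stats = gwas_sumstats(
      sim_stats_df(sc, beta_x_hat[, 1L], se_x[, 1L], truth$n_exposure[1L]),
      trait = "exposure_1", sample_n = truth$n_exposure[1L]),
    second_exposure_stats = gwas_sumstats(
      sim_stats_df(sc, beta_x_hat[, 2L], se_x[, 2L], truth$n_exposure[2L]),
      trait = "exposure_2", sample_n = truth$n_exposure[2L]),
    outcome_stats = gwas_sumstats(
      sim_stats_df(sc, beta_y_hat, se_y, truth$n_outcome),
      trait = "outcome", sample_n = truth$n_outcome),
    panel = identity_panel(sc),
    truth = truth,
    beta_x_true = beta_x_true, gamma_true = gamma_true, alpha = alpha
  ), class = "synthetic_study_pair")
}

#' @export
print.synthetic_study_pair <- function(x, ...) {
  cat("Synthetic study pair: ", x$truth$n_snps, " variants, theta = ",
      paste(signif(x$truth$theta, 4), collapse = ", "),
      ", pleiotropy: ", x$truth$pleiotropy_mode, "\n", sep = "")
  invisible(x)
}

#' Simulate a block-diagonal LD panel
#'
#' `n_blocks * block_size` variants with squared correlation `within_r2`
#' inside each block and 0 across blocks. Variants within a block are 10 kb
#' apart; blocks are separated by 2 Mb (beyond the default 1,000-kb clumping
#' window) on a rotating set of chromosomes.
#'
#' @param n_blocks,block_size panel geometry.
#' @param within_r2 squared correlation inside blocks, in `[0, 1]`.
#' @param seed unused placeholder kept for interface stability (the panel is
#'   deterministic in its geometry).
#' @return an [ld_panel()].
#' @export
simulate_ld_panel <- function(n_blocks, block_size, within_r2, seed = 1) {
  stopifnot(n_blocks >= 1, block_size >= 1, within_r2 >= 0, within_r2 <= 1)
  n <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  within <- rep(seq_len(block_size), times = n_blocks)
  rsid <- sprintf("rsB%03dS%03d", block, within)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((block - 1L) %/% 22L) * 2e6 + (within - 1L) * 1e4
  r2 <- matrix(0, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    r2[idx, idx] <- within_r2
  }
  diag(r2) <- 1
  ld_panel(rsid, r2, chrom, pos)
}
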