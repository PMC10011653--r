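# Univariable two-sample MR estimators: Wald ratio, IVW (fixed/random),
# MR-Egger, simple and weighted median, and odds-ratio reporting.

Z95 <- stats::qnorm(0.975)

#' Construct an MR estimate object
#'
#' @param method estimator label.
#' @param theta causal effect estimate on the log-odds scale.
#' @param se standard error of `theta`.
#' @param n_snps number of instruments used.
#' @param model_note free-text note (e.g. the variance model used).
#' @return An object of class `mr_estimate` with `theta`, `se`, 95% CI bounds,
#'   two-sided p-value, and the exponentiated (odds-ratio) scale.
#' @export
mr_estimate <- function(method, theta, se, n_snps, model_note = "") {
  stopifnot(se > 0)
  orr <- to_odds_ratio(theta, se)
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
                 pvalue = orr$pvalue, or_ = orr$or_,
                 or_ci_low = orr$ci_low, or_ci_high = orr$ci_high,
                 n_snps = n_snps, model_note = model_note),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs%s)\n", x$method, x$n_snps,
              if (nzchar(x$model_note)) paste0(", ", x$model_note) else ""))
  cat(sprintf("  theta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$theta, x$se, x$or_, x$or_ci_low, x$or_ci_high, x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, theta = x$theta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             or_ = x$or_, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             pvalue = x$pvalue, model_note = x$model_note,
             stringsAsFactors = FALSE)
}

#' Convert a log-odds effect and SE to odds-ratio reporting scale
#'
#' @param theta log-odds effect estimate.
#' @param se standard error, `> 0`.
#' @return list with `or_` (`exp(theta)`), `ci_low`/`ci_high`
#'   (`exp(theta -/+ 1.96 se)`), and the two-sided normal `pvalue`.
#' @export
to_odds_ratio <- function(theta, se) {
  stopifnot(se > 0)
  list(or_ = exp(theta),
       ci_low = exp(theta - Z95 * se),
       ci_high = exp(theta + Z95 * se),
       pvalue = 2 * stats::pnorm(-abs(theta / se)))
}

#' Per-variant Wald ratio
#'
#' Single-instrument causal estimate: the variant-outcome effect divided by
#' the variant-exposure effect, with a first-order delta-method standard
#' error that ignores uncertainty in the exposure effect.
#'
#' @param beta_x variant-exposure effect, nonzero.
#' @param beta_y variant-outcome effect.
#' @param se_y standard error of `beta_y`.
#' @return list with `theta = beta_y / beta_x` and `se = se_y / |beta_x|`.
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (beta_x == 0) stop("Wald ratio undefined for beta_x = 0", call. = FALSE)
  list(theta = beta_y / beta_x, se = se_y / abs(beta_x))
}

# Per-SNP Wald ratios with first-order SEs and inverse-variance weights.
# Variants with zero exposure beta are excluded (with a message).
ratio_set <- function(data) {
  zero <- data$beta_exposure == 0
  if (any(zero)) {
    message(sum(zero), " variant(s) with zero exposure effect excluded")
  }
  bx <- data$beta_exposure[!zero]
  by <- data$beta_outcome[!zero]
  sy <- data$se_outcome[!zero]
  ses <- sy / abs(bx)
  list(rsids = data$rsids[!zero], ratios = by / bx, ratio_ses = ses,
       weights = 1 / ses^2,
       beta_exposure = bx, beta_outcome = by, se_outcome = sy,
       se_exposure = data$se_exposure[!zero])
}

# Weighted least squares via explicit normal equations; returns coefficients,
# unscaled covariance, and weighted residual sum of squares.
wls_fit <- function(x, y, w) {
  x <- as.matrix(x)
  xtwx <- crossprod(x, x * w)
  xtwy <- crossprod(x, y * w)
  qrx <- qr(xtwx)
  if (qrx$rank < ncol(x)) stop("design matrix is rank deficient",
                               call. = FALSE)
  coef <- drop(solve(qrx, xtwy))
  resid <- y - drop(x %*% coef)
  list(coef = coef, cov_unscaled = solve(xtwx), rss = sum(w * resid^2),
       resid = resid)
}

#' Inverse-variance weighted estimator
#'
#' Combines per-variant Wald ratios with inverse-variance weights
#' `w_j = beta_xj^2 / se_yj^2`, equivalent to a zero-intercept weighted
#' regression of outcome betas on exposure betas. The fixed-effects SE is
#' `(sum w_j)^(-1/2)`; the multiplicative random-effects model scales it by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's heterogeneity statistic.
#' Under `model = "auto"` the random-effects scaling is applied when the Q
#' test rejects at the 0.05 level. A single-variant input falls back to the
#' Wald ratio.
#'
#' @param data a `harmonized_data` object.
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @return an [mr_estimate()] with method `"IVW"`; the Q statistic, its df
#'   and p-value are attached as attribute `"q"`.
#' @export
ivw <- function(data, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  rs <- ratio_set(data)
  j <- length(rs$ratios)
  if (j == 0L) stop("no usable variants", call. = FALSE)
  if (j == 1L) {
    wr <- wald_ratio(rs$beta_exposure, rs$beta_outcome, rs$se_outcome)
    est <- mr_estimate("IVW", wr$theta, wr$se, 1L,
                       model_note = "single SNP: Wald ratio")
    attr(est, "q") <- list(q_statistic = 0, df = NA_integer_,
                           pvalue = NA_real_)
    return(est)
  }
  w <- rs$weights
  theta <- sum(w * rs$ratios) / sum(w)
  q <- sum(w * (rs$ratios - theta)^2)
  q_p <- stats::pchisq(q, df = j - 1, lower.tail = FALSE)
  se_fixed <- 1 / sqrt(sum(w))
  scale <- max(1, sqrt(q / (j - 1)))
  use_random <- switch(model,
                       fixed = FALSE,
                       random = TRUE,
                       auto = is.finite(q_p) && q_p < 0.05)
  se <- if (use_random) se_fixed * scale else se_fixed
  note <- if (use_random) "multiplicative random effects" else "fixed effects"
  est <- mr_estimate("IVW", theta, se, j, model_note = note)
  attr(est, "q") <- list(q_statistic = q, df = j - 1L, pvalue = q_p)
  est
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an
#' unconstrained intercept, after orienting every variant so its exposure
#' beta is non-negative. The slope is a causal estimate robust to directional
#' pleiotropy under the InSIDE assumption; a nonzero intercept indicates
#' directional pleiotropy. Standard errors use multiplicative random-effects
#' scaling `max(1, sqrt(Q_egger / (J - 2)))`.
#'
#' @param data a `harmonized_data` object with at least 3 variants.
#' @return list with `slope` (an [mr_estimate()], method `"MR-Egger"`),
#'   `intercept_estimate`, `intercept_se`, `intercept_p`, and the Egger
#'   residual heterogeneity `q_statistic`/`df`/`q_pvalue`.
#' @export
mr_egger <- function(data) {
  rs <- ratio_set(data)
  j <- length(rs$ratios)
  if (j < 3L) stop("MR-Egger requires at least 3 variants", call. = FALSE)
  flip <- rs$beta_exposure < 0
  bx <- abs(rs$beta_exposure)
  by <- ifelse(flip, -rs$beta_outcome, rs$beta_outcome)
  w <- 1 / rs$se_outcome^2
  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w)
  scale <- max(1, sqrt(fit$rss / (j - 2)))
  ses <- sqrt(diag(fit$cov_unscaled)) * scale
  slope <- mr_estimate("MR-Egger", fit$coef[["slope"]], ses[[2L]], j,
                       model_note = "multiplicative random effects")
  list(slope = slope,
       intercept_estimate = fit$coef[["intercept"]],
       intercept_se = ses[[1L]],
       intercept_p = 2 * stats::pnorm(-abs(fit$coef[["intercept"]] /
                                             ses[[1L]])),
       q_statistic = fit$rss, df = j - 2L,
       q_pvalue = stats::pchisq(fit$rss, df = j - 2, lower.tail = FALSE))
}

# Run fn with a private RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Weighted median of ratios: order ascending, form centred cumulative
# normalized weights s_j = cumsum(w)_j - w_j / 2, and interpolate linearly
# across the ratios whose s_j bracket 0.5. Reduces to the usual
# mean-of-central-pair simple median under equal weights.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1L] >= 0.5) return(r[1L])
  j <- length(r)
  if (s[j] <= 0.5) return(r[j])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1L] - r[below]) * (0.5 - s[below]) /
    (s[below + 1L] - s[below])
}

# Parametric-bootstrap SE of a median-type point estimator: resample exposure
# and outcome betas from their estimated sampling distributions and take the
# SD of the re-estimated medians.
median_boot_se <- function(rs, point_fn, n_boot, seed) {
  j <- length(rs$ratios)
  with_local_seed(seed, function() {
    meds <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, rs$beta_exposure, rs$se_exposure)
      by <- stats::rnorm(j, rs$beta_outcome, rs$se_outcome)
      ok <- bx != 0
      point_fn(by[ok] / bx[ok], (abs(bx[ok]) / rs$se_outcome[ok])^2)
    }, numeric(1))
    stats::sd(meds)
  })
}

#' Simple median estimator
#'
#' The unweighted median of the per-variant Wald ratios (the mean of the two
#' central ratios for an even count); consistent when at least half of the
#' instruments are valid. The SE comes from a parametric bootstrap that
#' resamples both exposure and outcome betas from their estimated sampling
#' distributions.
#'
#' @param data a `harmonized_data` object with at least 3 variants.
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an [mr_estimate()] with method `"Simple median"`.
#' @export
simple_median <- function(data, n_boot = 1000, seed) {
  rs <- ratio_set(data)
  j <- length(rs$ratios)
  if (j < 3L) stop("median estimators require at least 3 variants",
                   call. = FALSE)
  theta <- stats::median(rs$ratios)
  se <- median_boot_se(rs, function(r, w) stats::median(r), n_boot, seed)
  mr_estimate("Simple median", theta, se, j,
              model_note = sprintf("bootstrap se (%d reps)", n_boot))
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when instruments carrying at least half of the total weight are
#' valid. Bootstrap SE as in [simple_median()].
#'
#' @inheritParams simple_median
#' @return an [mr_estimate()] with method `"Weighted median"`.
#' @export
weighted_median <- function(data, n_boot = 1000, seed) {
  rs <- ratio_set(data)
  j <- length(rs$ratios)
  if (j < 3L) stop("median estimators require at least 3 variants",
                   call. = FALSE)
  theta <- weighted_median_point(rs$ratios, rs$weights)
  se <- median_boot_se(rs, weighted_median_point, n_boot, seed)
  mr_estimate("Weighted median", theta, se, j,
              model_note = sprintf("bootstrap se (%d reps)", n_boot))
}
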