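# Multivariable MR: IVW and Egger multiple regressions, lasso-based invalid
# instrument selection (MR-Lasso), and the multivariable Cochran Q.

mv_check <- function(data, min_excess = 1L) {
  stopifnot(inherits(data, "mv_harmonized_data"))
  j <- nrow(data$beta_exposures)
  k <- ncol(data$beta_exposures)
  if (j < k + min_excess) {
    stop("need more variants (J = ", j, ") than parameters (", k + min_excess -
           1L, ")", call. = FALSE)
  }
  list(j = j, k = k)
}

mv_rank_check <- function(x, w, labels) {
  xs <- x * sqrt(w)
  if (qr(xs)$rank < ncol(x)) {
    stop("exposure beta matrix is rank deficient; collinear exposures: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  if (ncol(x) > 1L) {
    cc <- stats::cor(x)
    high <- abs(cc[upper.tri(cc)]) > 0.98
    if (any(high)) {
      warning("near-collinear exposure betas (|cor| > 0.98): estimates are ",
              "unstable", call. = FALSE)
    }
  }
  invisible(TRUE)
}

mv_estimate_from_fit <- function(coef, ses, labels, method, j, q, q_df,
                                 extra = list()) {
  per <- lapply(seq_along(labels), function(k) {
    mr_estimate(method, unname(coef[k]), unname(ses[k]), j,
                model_note = labels[k])
  })
  names(per) <- labels
  structure(c(list(method = method, exposures = per, n_snps = j,
                   q_statistic = q, q_df = q_df,
                   q_p = stats::pchisq(q, df = q_df, lower.tail = FALSE)),
              extra),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs)\n", x$method, x$n_snps))
  for (lbl in names(x$exposures)) {
    e <- x$exposures[[lbl]]
    cat(sprintf("  %s: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                lbl, e$or_, e$or_ci_low, e$or_ci_high, e$pvalue))
  }
  if (!is.null(x$intercept_estimate)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept_estimate, x$intercept_se, x$intercept_p))
  }
  if (!is.null(x$lasso_lambda)) {
    cat(sprintf("  lambda = %.4g, retained %d of %d SNPs\n",
                x$lasso_lambda, x$n_retained, x$n_snps))
  }
  cat(sprintf("  Q = %.3f on %d df, p = %.3g\n", x$q_statistic, x$q_df,
              x$q_p))
  invisible(x)
}

#' @export
as.data.frame.mvmr_estimate <- function(x, ...) {
  do.call(rbind, lapply(names(x$exposures), function(lbl) {
    e <- x$exposures[[lbl]]
    data.frame(method = x$method, exposure = lbl, n_snps = x$n_snps,
               theta = e$theta, se = e$se, or_ = e$or_,
               or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  }))
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression of outcome betas on all exposure-beta columns
#' without an intercept, weights `1 / se_yj^2`. Each coefficient is the
#' direct effect of that exposure conditional on the others. SEs use
#' multiplicative random-effects scaling `max(1, sqrt(Q / (J - K)))`.
#'
#' @param data an `mv_harmonized_data` object with J > K.
#' @return an `mvmr_estimate` with one [mr_estimate()] per exposure and the
#'   joint-fit Q statistic.
#' @export
mvmr_ivw <- function(data) {
  dim <- mv_check(data, 1L)
  x <- data$beta_exposures
  w <- 1 / data$se_outcome^2
  mv_rank_check(x, w, data$exposure_labels)
  fit <- wls_fit(x, data$beta_outcome, w)
  scale <- max(1, sqrt(fit$rss / (dim$j - dim$k)))
  ses <- sqrt(diag(fit$cov_unscaled)) * scale
  mv_estimate_from_fit(fit$coef, ses, data$exposure_labels, "MVMR-IVW",
                       dim$j, fit$rss, dim$j - dim$k)
}

#' Multivariable MR-Egger estimator
#'
#' As [mvmr_ivw()] but with an unconstrained intercept, after orienting every
#' variant so its first-exposure beta is non-negative (the anchor exposure is
#' the first column, so exposure order matters and is part of the analysis
#' configuration). SE scaling uses df `J - K - 1`.
#'
#' @param data an `mv_harmonized_data` object with J > K + 1.
#' @return an `mvmr_estimate` with intercept estimate/se/p attached.
#' @export
mvmr_egger <- function(data) {
  dim <- mv_check(data, 2L)
  flip <- data$beta_exposures[, 1L] < 0
  sgn <- ifelse(flip, -1, 1)
  x <- data$beta_exposures * sgn
  y <- data$beta_outcome * sgn
  w <- 1 / data$se_outcome^2
  mv_rank_check(x, w, data$exposure_labels)
  fit <- wls_fit(cbind(`(intercept)` = 1, x), y, w)
  scale <- max(1, sqrt(fit$rss / (dim$j - dim$k - 1)))
  ses <- sqrt(diag(fit$cov_unscaled)) * scale
  est <- mv_estimate_from_fit(
    fit$coef[-1L], ses[-1L], data$exposure_labels, "MVMR-Egger",
    dim$j, fit$rss, dim$j - dim$k - 1L,
    extra = list(intercept_estimate = unname(fit$coef[1L]),
                 intercept_se = unname(ses[1L]),
                 intercept_p = 2 * stats::pnorm(
                   -abs(fit$coef[1L] / ses[1L]))))
  est
}

#' Multivariable Cochran Q
#'
#' Weighted residual sum of squares from the [mvmr_ivw()] fit on J - K
#' degrees of freedom.
#'
#' @param data an `mv_harmonized_data` object with J > K.
#' @return a `q_result` (as [cochran_q()]).
#' @export
mvmr_q <- function(data) {
  est <- mvmr_ivw(data)
  structure(list(q_statistic = est$q_statistic, df = est$q_df,
                 pvalue = est$q_p), class = "q_result")
}

mv_subset <- function(data, keep) {
  out <- data
  out$rsids <- data$rsids[keep]
  out$beta_exposures <- data$beta_exposures[keep, , drop = FALSE]
  out$se_exposures <- data$se_exposures[keep, , drop = FALSE]
  out$beta_outcome <- data$beta_outcome[keep]
  out$se_outcome <- data$se_outcome[keep]
  out$eaf_anchor <- data$eaf_anchor[keep]
  out
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Penalized fit: minimize 0.5 * sum w_j (y_j - x_j' theta - alpha_j)^2 +
# lambda * sum |alpha_j| over (theta, alpha), slopes unpenalized. Alternates
# exact coordinate updates: alpha_j = soft(y_j - x_j'theta, lambda / w_j)
# given theta, then theta = WLS of (y - alpha) on X given alpha.
lasso_path_fit <- function(x, y, w, lambda, theta0, alpha0,
                           tol = 1e-8, max_sweeps = 10000) {
  theta <- theta0
  alpha <- alpha0
  for (it in seq_len(max_sweeps)) {
    r <- y - drop(x %*% theta)
    alpha_new <- soft_threshold(r, lambda / w)
    theta_new <- wls_fit(x, y - alpha_new, w)$coef
    delta <- max(abs(c(theta_new - theta, alpha_new - alpha)))
    theta <- theta_new
    alpha <- alpha_new
    if (delta < tol) break
  }
  list(theta = theta, alpha = alpha)
}

#' MR-Lasso: invalid-instrument selection by penalized pleiotropy intercepts
#'
#' Augments the multivariable IVW regression with one pleiotropy intercept
#' per variant, penalized by an L1 term (exposure slopes unpenalized). Along
#' a descending grid of penalty values, variants whose intercept is shrunk
#' exactly to zero form the valid set. The tuning value is chosen by a
#' heterogeneity stopping rule: scanning from the fully-penalized end of the
#' grid (all variants valid) toward the saturated end, the first penalty
#' whose valid set yields a Cochran Q below the 0.05 chi-square critical
#' value for its degrees of freedom is selected; if no penalty qualifies,
#' the one minimizing Q is used. The reported estimate is [mvmr_ivw()]
#' restricted to the valid set.
#'
#' @param data an `mv_harmonized_data` object with J > K.
#' @param lambda_grid `"auto"` (50 log-spaced values spanning the path from
#'   all-valid to saturated) or a numeric vector of penalty values.
#' @return an `mvmr_estimate` with method `"MR-Lasso"`, plus `lasso_lambda`,
#'   `n_retained`, and `valid_rsids`.
#' @export
mr_lasso <- function(data, lambda_grid = "auto") {
  dim <- mv_check(data, 1L)
  x <- data$beta_exposures
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  mv_rank_check(x, w, data$exposure_labels)
  base <- wls_fit(x, y, w)
  if (identical(lambda_grid, "auto")) {
    lam_max <- max(w * abs(base$resid)) * 1.05
    if (lam_max <= 0) {
      # perfect fit: no heterogeneity, every variant valid at any penalty
      est <- mvmr_ivw(data)
      est$method <- "MR-Lasso"
      for (lbl in names(est$exposures)) {
        est$exposures[[lbl]]$method <- "MR-Lasso"
      }
      est$lasso_lambda <- Inf
      est$n_retained <- dim$j
      est$valid_rsids <- data$rsids
      return(est)
    }
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * 1e-4),
                           length.out = 50))
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)

  theta <- base$coef
  alpha <- rep(0, dim$j)
  candidates <- list()
  for (lam in lambda_grid) {
    fit <- lasso_path_fit(x, y, w, lam, theta, alpha)
    theta <- fit$theta
    alpha <- fit$alpha
    valid <- which(alpha == 0)
    if (length(valid) < dim$k + 2L) next
    sub <- mv_subset(data, valid)
    # small interim subsets can look collinear by chance; only the final
    # chosen fit should surface that warning
    qres <- suppressWarnings(mvmr_q(sub))
    candidates[[length(candidates) + 1L]] <- list(
      lambda = lam, valid = valid, q = qres$q_statistic, df = qres$df,
      crit = stats::qchisq(0.95, df = qres$df))
  }
  if (length(candidates) == 0L) {
    stop("fewer than K + 2 valid variants at every penalty value",
         call. = FALSE)
  }
  passing <- Filter(function(cand) cand$q <= cand$crit, candidates)
  chosen <- if (length(passing) > 0L) {
    passing[[1L]]  # grid scanned in decreasing lambda: largest qualifying
  } else {
    candidates[[which.min(vapply(candidates, `[[`, numeric(1), "q"))]]
  }
  est <- mvmr_ivw(mv_subset(data, chosen$valid))
  est$method <- "MR-Lasso"
  for (lbl in names(est$exposures)) est$exposures[[lbl]]$method <- "MR-Lasso"
  est$lasso_lambda <- chosen$lambda
  est$n_retained <- length(chosen$valid)
  est$n_snps <- dim$j
  est$valid_rsids <- data$rsids[chosen$valid]
  est
}
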