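# Heterogeneity and pleiotropy diagnostics: Cochran Q, Egger intercept test,
# leave-one-out analysis, and MR-PRESSO (global, outlier, distortion tests).

#' Cochran Q heterogeneity test for the IVW fit
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` over the per-variant Wald ratios,
#' with inverse-variance weights and the fixed-effects IVW pooled estimate;
#' referred to a chi-square distribution on J - 1 degrees of freedom.
#'
#' @param data a `harmonized_data` object with at least 2 variants.
#' @return An object of class `q_result`: list with `q_statistic`, `df`,
#'   `pvalue`.
#' @export
cochran_q <- function(data) {
  rs <- ratio_set(data)
  j <- length(rs$ratios)
  if (j < 2L) stop("Cochran Q requires at least 2 variants", call. = FALSE)
  w <- rs$weights
  theta <- sum(w * rs$ratios) / sum(w)
  q <- sum(w * (rs$ratios - theta)^2)
  structure(list(q_statistic = q, df = j - 1L,
                 pvalue = stats::pchisq(q, df = j - 1, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f, df = %d, p = %.3g\n",
              x$q_statistic, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param data a `harmonized_data` object with at least 3 variants.
#' @return list with `intercept`, `se`, `pvalue` (two-sided normal).
#' @export
egger_intercept_test <- function(data) {
  fit <- mr_egger(data)
  list(intercept = fit$intercept_estimate, se = fit$intercept_se,
       pvalue = fit$intercept_p)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW (auto model) effect J times, each excluding one
#' variant, to show whether any single instrument drives the pooled result.
#'
#' @param data a `harmonized_data` object with at least 3 variants.
#' @return An object of class `loo_table`: a data.frame sorted by excluded
#'   rsid with columns `excluded_rsid`, `theta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_snps`; the full-sample estimate is attached as attribute
#'   `"full"`.
#' @export
leave_one_out <- function(data) {
  j <- length(data$rsids)
  if (j < 3L) stop("leave-one-out requires at least 3 variants",
                   call. = FALSE)
  subset_hd <- function(keep) {
    out <- data
    for (fld in c("rsids", "beta_exposure", "se_exposure", "beta_outcome",
                  "se_outcome", "eaf_exposure")) {
      out[[fld]] <- data[[fld]][keep]
    }
    out
  }
  rows <- lapply(seq_len(j), function(i) {
    est <- ivw(subset_hd(seq_len(j) != i))
    data.frame(excluded_rsid = data$rsids[i], theta = est$theta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, n_snps = est$n_snps,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$excluded_rsid), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("loo_table", "data.frame"),
            full = ivw(data))
}

# Leave-one-out fixed-effects IVW slopes in regression form, computed in O(J)
# from the full weighted sums. w is the regression weight 1 / se_y^2.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based test for horizontal pleiotropy. The observed residual sum
#' of squares `RSS = sum_j w_j (beta_yj - theta_(-j) beta_xj)^2` (with
#' `theta_(-j)` the leave-one-out IVW slope and `w_j = 1 / se_yj^2`) is
#' compared with its distribution under a no-pleiotropy model in which
#' exposure and outcome betas are redrawn from their estimated sampling
#' distributions. Per-variant residual contributions give an outlier test
#' (Bonferroni-adjusted across variants); variants flagged at `outlier_alpha`
#' are removed and the IVW estimate re-fitted. A distortion test compares the
#' observed change in estimate against removals of random variant subsets of
#' the same size.
#'
#' @param data a `harmonized_data` object with at least 4 variants.
#' @param n_sim number of simulated datasets, at least 100; default 1000.
#' @param outlier_alpha significance level applied to Bonferroni-adjusted
#'   per-variant p-values; default 0.05.
#' @param seed RNG seed (required).
#' @param n_distortion random subsets for the distortion test; default 1000.
#' @return An object of class `presso_result`: list with `global_rss`,
#'   `global_p`, `outlier_indices`, `outlier_rsids`, `outlier_pvalues`
#'   (Bonferroni-adjusted, named by rsid), `corrected` ([mr_estimate()] on the
#'   unflagged variants), `distortion_p` (`NA` when no outliers), `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed,
                      n_distortion = 1000) {
  j <- length(data$rsids)
  if (j < 4L) stop("MR-PRESSO requires at least 4 variants", call. = FALSE)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)
  if (missing(seed)) stop("mr_presso requires an explicit seed",
                          call. = FALSE)
  bx <- data$beta_exposure
  by <- data$beta_outcome
  sx <- data$se_exposure
  sy <- data$se_outcome
  w <- 1 / sy^2

  theta_loo <- loo_slopes(bx, by, w)
  obs_contrib <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(obs_contrib)

  sim <- with_local_seed(seed, function() {
    bx_sim <- matrix(stats::rnorm(j * n_sim, bx, sx), nrow = j)
    by_sim <- matrix(stats::rnorm(j * n_sim, theta_loo * bx, sy), nrow = j)
    sxy <- colSums(w * bx_sim * by_sim)
    sxx <- colSums(w * bx_sim^2)
    th_loo_sim <- (rep(sxy, each = j) - w * bx_sim * by_sim) /
      (rep(sxx, each = j) - w * bx_sim^2)
    contrib <- w * (by_sim - th_loo_sim * bx_sim)^2
    list(rss = colSums(contrib), contrib = contrib)
  })

  global_p <- mean(sim$rss >= rss_obs)
  p_per <- rowMeans(sim$contrib >= obs_contrib)
  p_adj <- stats::setNames(pmin(1, p_per * j), data$rsids)
  flagged <- which(p_adj < outlier_alpha)

  subset_hd <- function(keep) {
    out <- data
    for (fld in c("rsids", "beta_exposure", "se_exposure", "beta_outcome",
                  "se_outcome", "eaf_exposure")) {
      out[[fld]] <- data[[fld]][keep]
    }
    out
  }
  original <- ivw(data)
  if (length(flagged) == 0L) {
    corrected <- original
    distortion_p <- NA_real_
  } else {
    if (length(flagged) >= j - 1L) {
      stop("MR-PRESSO flagged nearly all variants; diagnostics unreliable",
           call. = FALSE)
    }
    corrected <- ivw(subset_hd(setdiff(seq_len(j), flagged)))
    d_obs <- corrected$theta - original$theta
    distortion_p <- with_local_seed(seed + 1L, function() {
      m <- length(flagged)
      d_sim <- vapply(seq_len(n_distortion), function(b) {
        drop_idx <- sample.int(j, m)
        ivw_theta_subset(bx, by, w, setdiff(seq_len(j), drop_idx)) -
          original$theta
      }, numeric(1))
      mean(abs(d_sim) >= abs(d_obs))
    })
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_indices = unname(flagged),
                 outlier_rsids = data$rsids[flagged],
                 outlier_pvalues = p_adj,
                 corrected = corrected, original = original,
                 distortion_p = distortion_p,
                 n_sim = n_sim, outlier_alpha = outlier_alpha, seed = seed),
            class = "presso_result")
}

# Fixed-effects IVW slope on an index subset (distortion-test helper).
ivw_theta_subset <- function(bx, by, w, keep) {
  sum(w[keep] * bx[keep] * by[keep]) / sum(w[keep] * bx[keep]^2)
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d): global RSS = %.3f, p = %.3g\n",
              x$n_sim, x$global_rss, x$global_p))
  if (length(x$outlier_indices) == 0L) {
    cat("  no outliers flagged\n")
  } else {
    cat("  outliers: ", paste(x$outlier_rsids, collapse = ", "),
        sprintf("\n  distortion test p = %.3g\n", x$distortion_p), sep = "")
    cat(sprintf("  corrected OR = %.3f (95%% CI %.3f-%.3f)\n",
                x$corrected$or_, x$corrected$or_ci_low,
                x$corrected$or_ci_high))
  }
  invisible(x)
}
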