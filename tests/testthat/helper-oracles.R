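# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately coded through different routes than the package
# (lm() fits, exhaustive scans) so agreement is a genuine cross-check.

# Zero-intercept weighted least squares via lm().
oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  j <- length(bx)
  se_unscaled <- s$coefficients[1, 2] / s$sigma
  rss <- sum((1 / sy^2) * residuals(fit)^2)
  list(theta = unname(coef(fit)[1]), se_fixed = se_unscaled,
       se_random = se_unscaled * max(1, sqrt(rss / (j - 1))), q = rss)
}

# Two-parameter weighted least squares via lm(), exposure-orientation applied.
oracle_egger <- function(bx, by, sy) {
  flip <- bx < 0
  bx2 <- abs(bx); by2 <- ifelse(flip, -by, by)
  fit <- lm(by2 ~ bx2, weights = 1 / sy^2)
  s <- summary(fit)
  j <- length(bx)
  rss <- sum((1 / sy^2) * residuals(fit)^2)
  scale <- max(1, sqrt(rss / (j - 2)))
  se_unscaled <- s$coefficients[, 2] / s$sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       slope_se = unname(se_unscaled[2]) * scale,
       intercept_se = unname(se_unscaled[1]) * scale, q = rss)
}

# Multivariable weighted least squares via lm() on K columns (+ intercept).
oracle_mvmr <- function(x, y, sy, intercept = FALSE) {
  w <- 1 / sy^2
  df_model <- ncol(x) + intercept
  fit <- if (intercept) lm(y ~ x, weights = w) else lm(y ~ 0 + x, weights = w)
  s <- summary(fit)
  rss <- sum(w * residuals(fit)^2)
  scale <- max(1, sqrt(rss / (nrow(x) - df_model)))
  list(coef = unname(coef(fit)), se = unname(s$coefficients[, 2] / s$sigma) *
         scale, q = rss)
}

# Brute-force greedy clump: literal restatement of the selection rule with
# explicit loops over all pairs.
oracle_clump <- function(df, r2, r2_threshold, window_kb) {
  remaining <- df[order(df$pvalue, df$rsid), , drop = FALSE]
  chosen <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    chosen <- c(chosen, top$rsid)
    keep <- rep(TRUE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      same_chr <- remaining$chrom[i] == top$chrom
      close <- abs(remaining$pos[i] - top$pos) <= window_kb * 1000
      linked <- r2[top$rsid, remaining$rsid[i]] > r2_threshold
      if (i == 1 || (same_chr && close && linked)) keep[i] <- FALSE
    }
    remaining <- remaining[keep, , drop = FALSE]
  }
  chosen
}

# Weighted median by direct scan of the cumulative-weight break point.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- NA
  for (i in seq_len(length(s) - 1)) if (s[i] < 0.5 && s[i + 1] >= 0.5) k <- i
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Random harmonized fixture around a true slope.
make_hd <- function(j, theta = 0.1, seed = 1, pleiotropy = 0) {
  set.seed(seed)
  bx <- runif(j, 0.05, 0.3) * sample(c(-1, 1), j, replace = TRUE)
  sx <- runif(j, 0.005, 0.02)
  sy <- runif(j, 0.01, 0.05)
  by <- theta * bx + rnorm(j, pleiotropy, 0) + rnorm(j, 0, sy)
  harmonized_data(bx, sx, by, sy)
}

# Small summary-stats data.frame with sensible defaults.
make_stats_df <- function(rsid, beta, se, pvalue,
                          chrom = "1", pos = seq_along(rsid) * 1e5,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, n = 10000) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}
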