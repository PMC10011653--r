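# Multivariable estimators: exact fits, reductions, oracles, MR-Lasso.

make_mv <- function(j, theta = c(0.08, 0.17), seed = 1, rho = 0.4,
                    alpha = rep(0, j)) {
  set.seed(seed)
  g1 <- rnorm(j)
  g2 <- rho * g1 + sqrt(1 - rho^2) * rnorm(j)
  x <- cbind(a = 0.1 * g1, b = 0.1 * g2)
  sy <- runif(j, 0.01, 0.03)
  y <- drop(x %*% theta) + alpha + rnorm(j, 0, sy)
  mv_harmonized_data(x, matrix(0.005, j, 2), y, sy,
                     exposure_labels = c("a", "b"))
}

test_that("MVMR-IVW recovers exact fits and matches the WLS oracle", {
  mv <- make_mv(20, seed = 2)
  exact_y <- drop(mv$beta_exposures %*% c(0.08, 0.17))
  mv_exact <- mv_harmonized_data(mv$beta_exposures, mv$se_exposures,
                                 exact_y, mv$se_outcome,
                                 exposure_labels = mv$exposure_labels)
  est <- mvmr_ivw(mv_exact)
  expect_equal(est$exposures$a$theta, 0.08, tolerance = 1e-12)
  expect_equal(est$exposures$b$theta, 0.17, tolerance = 1e-12)
  expect_equal(est$q_statistic, 0, tolerance = 1e-16)

  for (s in 1:20) {
    mv <- make_mv(50, seed = s)
    o <- oracle_mvmr(mv$beta_exposures, mv$beta_outcome, mv$se_outcome)
    got <- mvmr_ivw(mv)
    expect_equal(unname(c(got$exposures$a$theta, got$exposures$b$theta)),
                 o$coef, tolerance = 1e-10)
    expect_equal(unname(c(got$exposures$a$se, got$exposures$b$se)),
                 o$se, tolerance = 1e-10)
    expect_equal(got$q_statistic, o$q, tolerance = 1e-10)
  }
})

test_that("MVMR-Egger handles intercepts, shifts, and matches its oracle", {
  mv <- make_mv(20, seed = 3)
  # orient rows as the estimator will, then plant a constant intercept
  sgn <- ifelse(mv$beta_exposures[, 1] < 0, -1, 1)
  exact_y <- drop(mv$beta_exposures %*% c(0.08, 0.17))
  shifted_y <- (exact_y * sgn + 0.02) * sgn
  mv_shift <- mv_harmonized_data(mv$beta_exposures, mv$se_exposures,
                                 shifted_y, mv$se_outcome,
                                 exposure_labels = mv$exposure_labels)
  est <- mvmr_egger(mv_shift)
  expect_equal(est$intercept_estimate, 0.02, tolerance = 1e-12)
  expect_equal(est$exposures$a$theta, 0.08, tolerance = 1e-12)
  expect_equal(est$exposures$b$theta, 0.17, tolerance = 1e-12)

  for (s in 1:20) {
    mv <- make_mv(50, seed = 100 + s)
    sgn <- ifelse(mv$beta_exposures[, 1] < 0, -1, 1)
    o <- oracle_mvmr(mv$beta_exposures * sgn, mv$beta_outcome * sgn,
                     mv$se_outcome, intercept = TRUE)
    got <- mvmr_egger(mv)
    expect_equal(got$intercept_estimate, o$coef[1], tolerance = 1e-10)
    expect_equal(unname(c(got$exposures$a$theta, got$exposures$b$theta)),
                 o$coef[-1], tolerance = 1e-10)
    expect_equal(unname(c(got$intercept_se, got$exposures$a$se,
                          got$exposures$b$se)), o$se, tolerance = 1e-10)
  }
})

test_that("K = 1 multivariable estimators equal their univariable counterparts", {
  hd <- make_hd(30, theta = 0.1, seed = 31)
  mv1 <- mv_harmonized_data(matrix(hd$beta_exposure, ncol = 1),
                            matrix(hd$se_exposure, ncol = 1),
                            hd$beta_outcome, hd$se_outcome,
                            exposure_labels = "x")
  uni_r <- ivw(hd, model = "random")
  got <- mvmr_ivw(mv1)
  expect_equal(got$exposures$x$theta, uni_r$theta, tolerance = 1e-10)
  expect_equal(got$exposures$x$se, uni_r$se, tolerance = 1e-10)
  expect_equal(mvmr_q(mv1)$q_statistic, cochran_q(hd)$q_statistic,
               tolerance = 1e-10)

  eg_uni <- mr_egger(hd)
  eg_mv <- mvmr_egger(mv1)
  expect_equal(eg_mv$exposures$x$theta, eg_uni$slope$theta,
               tolerance = 1e-10)
  expect_equal(eg_mv$exposures$x$se, eg_uni$slope$se, tolerance = 1e-10)
  expect_equal(eg_mv$intercept_estimate, eg_uni$intercept_estimate,
               tolerance = 1e-10)
})

test_that("rank deficiency errors and near-collinearity warns", {
  x <- cbind(a = runif(10, 0.1, 0.2), b = 0)
  x[1, 2] <- 1e-14
  expect_error(mvmr_ivw(mv_harmonized_data(x, matrix(0.01, 10, 2),
                                           rnorm(10), rep(0.02, 10))),
               "rank deficient")
  set.seed(1)
  g <- rnorm(40)
  x2 <- cbind(a = 0.1 * g, b = 0.1 * (0.999 * g + sqrt(1 - 0.999^2) * rnorm(40)))
  expect_warning(mvmr_ivw(mv_harmonized_data(x2, matrix(0.01, 40, 2),
                                             rnorm(40, 0, 0.02),
                                             rep(0.02, 40))),
                 "near-collinear")
})

test_that("MR-Lasso reduces to MVMR-IVW at infinite penalty and to the exact
           fit at zero penalty on exact fixtures", {
  mv <- make_mv(25, seed = 7)
  full <- mvmr_ivw(mv)
  big_lambda <- mr_lasso(mv, lambda_grid = 1e6)
  expect_equal(big_lambda$exposures$a$theta, full$exposures$a$theta,
               tolerance = 1e-10)
  expect_equal(big_lambda$exposures$b$theta, full$exposures$b$theta,
               tolerance = 1e-10)
  expect_equal(big_lambda$n_retained, 25)

  # exact fixture: even the saturated end of the path keeps the true slopes
  exact_y <- drop(mv$beta_exposures %*% c(0.08, 0.17))
  mv_exact <- mv_harmonized_data(mv$beta_exposures, mv$se_exposures,
                                 exact_y, mv$se_outcome,
                                 exposure_labels = mv$exposure_labels)
  est0 <- mr_lasso(mv_exact)
  expect_equal(est0$exposures$a$theta, 0.08, tolerance = 1e-8)
  expect_equal(est0$exposures$b$theta, 0.17, tolerance = 1e-8)
})

test_that("MR-Lasso excludes planted pleiotropic SNPs and reduces heterogeneity", {
  n_rep <- 25
  hits <- numeric(n_rep)
  q_ok <- logical(n_rep)
  moved_closer <- logical(n_rep)
  theta_true <- c(0.08, 0.17)
  for (s in seq_len(n_rep)) {
    alpha <- rep(0, 30)
    planted <- c(4, 13, 27)
    alpha[planted] <- c(0.15, -0.18, 0.2)
    mv <- make_mv(30, theta = theta_true, seed = 700 + s, alpha = alpha)
    est <- mr_lasso(mv)
    excluded <- setdiff(seq_len(30), match(est$valid_rsids, mv$rsids))
    hits[s] <- mean(planted %in% excluded)
    qfull <- mvmr_q(mv)$q_statistic
    q_ok[s] <- est$q_statistic <= qfull + 1e-9
    full <- mvmr_ivw(mv)
    err_lasso <- abs(c(est$exposures$a$theta, est$exposures$b$theta) -
                       theta_true)
    err_full <- abs(c(full$exposures$a$theta, full$exposures$b$theta) -
                      theta_true)
    moved_closer[s] <- sum(err_lasso) <= sum(err_full) + 1e-12
  }
  expect_gte(mean(hits), 0.9)
  expect_true(all(q_ok))
  expect_gte(mean(moved_closer), 0.8)
})

test_that("multivariable estimates are invariant to consistent allele flips", {
  mv <- make_mv(30, seed = 55)
  flip <- rep(c(TRUE, FALSE), 15)
  sgn <- ifelse(flip, -1, 1)
  mv_flip <- mv_harmonized_data(mv$beta_exposures * sgn, mv$se_exposures,
                                mv$beta_outcome * sgn, mv$se_outcome,
                                exposure_labels = mv$exposure_labels)
  a <- mvmr_ivw(mv); b <- mvmr_ivw(mv_flip)
  expect_equal(b$exposures$a$theta, a$exposures$a$theta, tolerance = 1e-12)
  expect_equal(b$q_statistic, a$q_statistic, tolerance = 1e-10)
  ea <- mvmr_egger(mv); eb <- mvmr_egger(mv_flip)
  expect_equal(eb$exposures$a$theta, ea$exposures$a$theta, tolerance = 1e-12)
  expect_equal(eb$intercept_estimate, ea$intercept_estimate,
               tolerance = 1e-12)
})
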