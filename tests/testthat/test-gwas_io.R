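# Data model, file round-trips, and allele harmonization.

test_that("reader validates rows, counts drops, and round-trips canonically", {
  df <- make_stats_df(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                      se = c(0.01, 0.02, 0.01), pvalue = c(1e-9, 1e-5, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(gwas_sumstats(df, "t2d"), path)
  stats <- read_summary_stats(path, trait = "t2d")
  expect_equal(n_variants(stats), 3)
  expect_equal(load_report(stats)$n_dropped, 0)
  expect_equal(stats$data$beta, df$beta)

  # byte-identical canonical round-trip
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(stats, path2)
  expect_identical(readLines(path2), readLines(path))

  # invariant enforcement: se = 0 row is dropped and counted
  bad <- df
  bad$se[2] <- 0
  s2 <- gwas_sumstats(bad, "t2d")
  expect_equal(n_variants(s2), 2)
  expect_equal(load_report(s2)$n_dropped, 1)
  expect_equal(load_report(s2)$drop_reasons[["non-positive se"]], 1)

  # zero valid rows is a data error
  allbad <- df
  allbad$se <- 0
  expect_error(gwas_sumstats(allbad, "t2d"), "no valid rows")
})

test_that("column_map remaps alias headers to the same parsed object", {
  df <- make_stats_df(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                      se = c(0.01, 0.02, 0.01), pvalue = c(1e-9, 1e-5, 0.3))
  canonical <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(gwas_sumstats(df, "t2d"), canonical)
  ref <- read_summary_stats(canonical, trait = "t2d")

  lines <- readLines(canonical)
  lines[1] <- "SNP\tCHR\tBP\tEA\tOA\tFREQ\tBETA\tSE\tP\tN"
  aliased <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, aliased)
  remapped <- read_summary_stats(
    aliased, trait = "t2d",
    column_map = c(rsid = "SNP", chrom = "CHR", pos = "BP",
                   effect_allele = "EA", other_allele = "OA", eaf = "FREQ",
                   beta = "BETA", se = "SE", pvalue = "P", n = "N"))
  expect_equal(remapped$data, ref$data)

  expect_error(read_summary_stats(aliased, trait = "t2d"),
               "required column")
  expect_error(read_summary_stats(aliased, trait = "t2d",
                                  column_map = c(bogus = "SNP")),
               "unknown field")
})

test_that("harmonize aligns orientations, flips swapped alleles, drops palindromes", {
  exp_df <- make_stats_df(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
                          se = 0.01, pvalue = 1e-9,
                          effect_allele = c("A", "A", "A"),
                          other_allele = c("G", "G", "T"), eaf = 0.3)
  # rs1 identical orientation; rs2 swapped alleles; rs3 palindromic at 0.50
  out_df <- make_stats_df(c("rs1", "rs2", "rs3"), beta = c(0.05, 0.2, 0.1),
                          se = 0.02, pvalue = 0.5,
                          effect_allele = c("A", "G", "A"),
                          other_allele = c("G", "A", "T"),
                          eaf = c(0.3, 0.7, 0.50))
  hd <- harmonize(gwas_sumstats(exp_df, "x"), gwas_sumstats(out_df, "y"),
                  palindrome_eaf_window = 0.08)
  expect_equal(hd$rsids, c("rs1", "rs2"))
  expect_equal(hd$beta_outcome, c(0.05, -0.2))
  expect_equal(hd$orientation_flips, 1)
  expect_equal(hd$n_dropped_palindromic, 1)
  # rows out + dropped = intersection
  expect_equal(length(hd$rsids) + nrow(hd$drop_log), 3)
})

test_that("harmonize resolves strand complements and is orientation invariant", {
  set.seed(42)
  pairs <- matrix(c("A", "G", "C", "T", "T", "G", "A", "C"), ncol = 2,
                  byrow = TRUE)
  j <- 40
  pick <- sample(4, j, replace = TRUE)
  exp_df <- make_stats_df(sprintf("rs%02d", 1:j), beta = rnorm(j, 0, 0.1),
                          se = 0.01, pvalue = 1e-9,
                          effect_allele = pairs[pick, 1],
                          other_allele = pairs[pick, 2],
                          eaf = runif(j, 0.1, 0.9))
  out_df <- exp_df
  out_df$beta <- rnorm(j, 0, 0.05)
  out_df$se <- 0.02

  # strand-complement representation of the same variants
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  strand <- out_df
  strand$effect_allele <- unname(comp[out_df$effect_allele])
  strand$other_allele <- unname(comp[out_df$other_allele])

  ex <- gwas_sumstats(exp_df, "x")
  hd_plain <- harmonize(ex, gwas_sumstats(out_df, "y"))
  hd_strand <- harmonize(ex, gwas_sumstats(strand, "y"))
  expect_equal(hd_strand$beta_outcome, hd_plain$beta_outcome)

  # flipping every outcome record's alleles and beta sign changes nothing
  flipped <- out_df
  flipped$effect_allele <- out_df$other_allele
  flipped$other_allele <- out_df$effect_allele
  flipped$beta <- -out_df$beta
  flipped$eaf <- 1 - out_df$eaf
  hd_flip <- harmonize(ex, gwas_sumstats(flipped, "y"))
  expect_equal(hd_flip$beta_outcome, hd_plain$beta_outcome)
  expect_equal(hd_flip$rsids, hd_plain$rsids)
})

test_that("harmonize is idempotent on an already-aligned pair", {
  pair <- simulate_univariable(simulation_truth(n_snps = 30, seed = 5))
  hd1 <- harmonize(pair$exposure_stats, pair$outcome_stats)
  expect_equal(hd1$orientation_flips, 0)
  expect_equal(hd1$beta_outcome, pair$outcome_stats$data$beta)
  hd2 <- harmonize(pair$exposure_stats, pair$outcome_stats)
  expect_identical(hd1, hd2)
})

test_that("harmonize_multi intersects studies and anchors on the first exposure", {
  exp1 <- make_stats_df(sprintf("rs%d", 1:5), beta = c(0.1, 0.2, 0.3, 0.1, 0.2),
                        se = 0.01, pvalue = 1e-9,
                        effect_allele = c("A", "A", "A", "A", "A"),
                        other_allele = c("G", "G", "G", "G", "T"),
                        eaf = c(0.3, 0.3, 0.3, 0.3, 0.2))
  exp2 <- exp1
  exp2$beta <- c(0.05, 0.1, 0.15, 0.05, 0.1)
  # outcome: rs2 swapped, rs5 palindromic near 0.5, rs4 absent
  out <- exp1[c(1, 2, 3, 5), ]
  out$beta <- c(0.02, 0.04, 0.06, 0.08)
  out$effect_allele[2] <- "G"; out$other_allele[2] <- "A"; out$eaf[2] <- 0.7
  out$eaf[4] <- 0.5
  mv <- harmonize_multi(list(gwas_sumstats(exp1, "x1"),
                             gwas_sumstats(exp2, "x2")),
                        gwas_sumstats(out, "y"))
  expect_equal(mv$rsids, c("rs1", "rs2", "rs3"))
  expect_equal(mv$beta_outcome, c(0.02, -0.04, 0.06))
  expect_equal(mv$orientation_flips, 1)
  expect_equal(mv$n_dropped_palindromic, 1)
  expect_equal(dim(mv$beta_exposures), c(3, 2))

  # identical second exposure gives equal beta columns
  mv2 <- harmonize_multi(list(gwas_sumstats(exp1, "x1"),
                              gwas_sumstats(exp1, "x1b")),
                         gwas_sumstats(out, "y"))
  expect_equal(mv2$beta_exposures[, 1], mv2$beta_exposures[, 2],
               ignore_attr = TRUE)
})

test_that("synthetic datasets round-trip through the reader unchanged", {
  pair <- simulate_univariable(simulation_truth(n_snps = 20, seed = 11))
  for (stats in list(pair$exposure_stats, pair$outcome_stats)) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_summary_stats(stats, path)
    back <- read_summary_stats(path, trait = stats$trait,
                               sample_n = stats$sample_n)
    expect_equal(back$data, stats$data, tolerance = 1e-12)
  }
})
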