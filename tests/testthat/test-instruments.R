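# Instrument selection and strength diagnostics.

test_that("significance filter retains exactly the sub-threshold records", {
  df <- make_stats_df(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                      pvalue = c(1e-9, 1e-7, 0.3))
  stats <- gwas_sumstats(df, "x")
  expect_equal(filter_genome_wide(stats, 5e-8)$data$rsid, "rs1")
  expect_equal(filter_genome_wide(stats, 1)$data$rsid, df$rsid)

  set.seed(3)
  big <- make_stats_df(sprintf("rs%04d", 1:1000), beta = 0.1, se = 0.01,
                       pvalue = 10^runif(1000, -12, 0))
  bigstats <- gwas_sumstats(big, "x")
  for (thr in c(5e-8, 1e-5, 1e-2)) {
    got <- filter_genome_wide(bigstats, thr)$data$rsid
    expect_equal(got, big$rsid[big$pvalue < thr])
  }
  # monotonicity: shrinking the threshold never increases the count
  counts <- vapply(10^seq(-10, -1), function(thr) {
    nrow(filter_genome_wide(bigstats, thr)$data)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_warning(filter_genome_wide(bigstats, 1e-15), "no variants")
})

test_that("greedy clumping keeps lowest-p index SNPs and prunes linked ones", {
  # independent panel: everything retained
  panel0 <- simulate_ld_panel(n_blocks = 6, block_size = 1, within_r2 = 0)
  df <- make_stats_df(panel0$rsids, beta = 0.1, se = 0.01,
                      pvalue = c(1e-10, 1e-9, 1e-8, 1e-12, 1e-9, 1e-11),
                      chrom = panel0$chrom, pos = panel0$pos)
  got <- ld_clump(gwas_sumstats(df, "x"), panel0)
  expect_setequal(got$data$rsid, df$rsid)

  # two linked SNPs 10 kb apart: only the smaller p survives
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  panel2 <- ld_panel(c("rsA", "rsB"), r2, c("1", "1"), c(1e6, 1e6 + 1e4))
  df2 <- make_stats_df(c("rsA", "rsB"), beta = 0.1, se = 0.01,
                       pvalue = c(1e-10, 1e-9), chrom = "1",
                       pos = c(1e6, 1e6 + 1e4))
  got2 <- ld_clump(gwas_sumstats(df2, "x"), panel2)
  expect_equal(got2$data$rsid, "rsA")
})

test_that("clumping matches the brute-force oracle and is order invariant", {
  set.seed(7)
  n <- 5
  rsids <- sprintf("rs%d", 1:n)
  m <- matrix(runif(n * n, 0, 0.9), n)
  r2 <- (m + t(m)) / 2
  diag(r2) <- 1
  panel <- ld_panel(rsids, r2, rep("1", n), seq(1e6, by = 2e5, length.out = n))
  df <- make_stats_df(rsids, beta = 0.1, se = 0.01,
                      pvalue = c(1e-10, 1e-9, 1e-9, 1e-12, 1e-8),
                      chrom = "1", pos = panel$pos)
  cfg <- clump_config(r2_threshold = 0.3, window_kb = 1000)
  got <- ld_clump(gwas_sumstats(df, "x"), panel, cfg)
  expect_equal(sort(got$data$rsid),
               sort(oracle_clump(df, panel$r2, 0.3, 1000)))

  # no retained pair within the window exceeds the r2 threshold
  kept <- got$data
  for (i in seq_len(nrow(kept))) {
    for (k in seq_len(nrow(kept))) {
      if (i >= k) next
      if (kept$chrom[i] == kept$chrom[k] &&
          abs(kept$pos[i] - kept$pos[k]) <= 1e6) {
        expect_lte(panel$r2[kept$rsid[i], kept$rsid[k]], 0.3)
      }
    }
  }

  # permuting the input record order does not change the result
  for (s in 1:5) {
    set.seed(s)
    perm <- df[sample(n), , drop = FALSE]
    got_perm <- ld_clump(gwas_sumstats(perm, "x"), panel, cfg)
    expect_equal(got_perm$data$rsid, got$data$rsid)
  }

  # ties in p are broken by lexicographic rsid, deterministically
  tie <- make_stats_df(c("rsZ", "rsA"), beta = 0.1, se = 0.01,
                       pvalue = c(1e-9, 1e-9), chrom = "1",
                       pos = c(1e6, 1e6 + 1e4))
  tie_panel <- ld_panel(c("rsZ", "rsA"), matrix(c(1, 0.9, 0.9, 1), 2),
                        c("1", "1"), c(1e6, 1e6 + 1e4))
  expect_equal(ld_clump(gwas_sumstats(tie, "x"), tie_panel)$data$rsid, "rsA")
})

test_that("joint clumping pools exposures by their minimum p-value", {
  panel <- simulate_ld_panel(n_blocks = 4, block_size = 1, within_r2 = 0)
  dfa <- make_stats_df(panel$rsids, beta = 0.1, se = 0.01,
                       pvalue = c(1e-10, 1e-9, 0.5, 0.5),
                       chrom = panel$chrom, pos = panel$pos)
  dfb <- make_stats_df(panel$rsids, beta = 0.1, se = 0.01,
                       pvalue = c(1e-12, 0.5, 1e-9, 0.5),
                       chrom = panel$chrom, pos = panel$pos)
  sa <- gwas_sumstats(dfa, "x1"); sb <- gwas_sumstats(dfb, "x2")
  joint <- clump_joint(list(sa, sb), panel)
  expect_setequal(joint$data$rsid, panel$rsids[1:3])
  # shared significant SNP appears once, at its smaller p
  expect_equal(joint$data$pvalue[joint$data$rsid == panel$rsids[1]], 1e-12)

  # an exposure contributing nothing reduces to univariable clumping
  null_b <- dfb
  null_b$pvalue <- 0.5
  joint2 <- clump_joint(list(sa, gwas_sumstats(null_b, "x2")), panel)
  uni <- ld_clump(suppressWarnings(filter_genome_wide(sa)), panel)
  expect_equal(sort(joint2$data$rsid), sort(uni$data$rsid))

  # hand-traced fixture with one shared correlated pair across exposures:
  # rsP (p 1e-12, exposure 2) prunes rsQ (p 1e-10, exposure 1)
  r2 <- diag(1, 3)
  r2[1, 2] <- r2[2, 1] <- 0.8
  tpanel <- ld_panel(c("rsP", "rsQ", "rsR"), r2, rep("1", 3),
                     c(1e6, 1.1e6, 9e6))
  e1 <- make_stats_df(c("rsQ", "rsR"), beta = 0.1, se = 0.01,
                      pvalue = c(1e-10, 1e-9), chrom = "1", pos = c(1.1e6, 9e6))
  e2 <- make_stats_df(c("rsP"), beta = 0.1, se = 0.01, pvalue = 1e-12,
                      chrom = "1", pos = 1e6)
  traced <- clump_joint(list(gwas_sumstats(e1, "x1"),
                             gwas_sumstats(e2, "x2")), tpanel)
  expect_setequal(traced$data$rsid, c("rsP", "rsR"))
})

test_that("instrument strength follows the 2p(1-p)beta^2 and (beta/se)^2 formulas", {
  df <- make_stats_df(c("rs1", "rs2"), beta = c(0.1, 0.2),
                      se = c(0.02, 0.05), pvalue = 1e-9, eaf = c(0.5, 0.2),
                      n = 10000)
  s <- instrument_strength(gwas_sumstats(df, "x"))
  expect_equal(s$r2_total, 2 * 0.25 * 0.01 + 2 * 0.16 * 0.04,
               tolerance = 1e-12)
  expect_equal(unname(s$f_per_snp[["rs1"]]), 25, tolerance = 1e-12)
  expect_equal(s$f_overall,
               s$r2_total * (10000 - 2 - 1) / ((1 - s$r2_total) * 2),
               tolerance = 1e-12)

  # R2 is invariant to flipping an effect allele
  flipped <- df
  flipped$beta <- -df$beta
  flipped$eaf <- 1 - df$eaf
  expect_equal(instrument_strength(gwas_sumstats(flipped, "x"))$r2_total,
               s$r2_total, tolerance = 1e-12)

  # missing eaf drops the SNP from R2 but keeps its F
  na_eaf <- df
  na_eaf$eaf[2] <- NA
  s2 <- instrument_strength(gwas_sumstats(na_eaf, "x"))
  expect_equal(s2$r2_total, 2 * 0.25 * 0.01, tolerance = 1e-12)
  expect_equal(s2$n_missing_eaf, 1)
  expect_length(s2$f_per_snp, 2)

  # tiny sample size makes the overall F undefined
  expect_error(instrument_strength(gwas_sumstats(df, "x"), n = 3),
               "overall F undefined")
})

test_that("LD panel files round-trip", {
  panel <- simulate_ld_panel(n_blocks = 3, block_size = 2, within_r2 = 0.7)
  r2p <- withr::local_tempfile(fileext = ".tsv")
  posp <- withr::local_tempfile(fileext = ".tsv")
  write_ld_panel(panel, r2p, posp)
  back <- read_ld_panel(r2p, posp)
  expect_equal(back$rsids, panel$rsids)
  expect_equal(back$r2, panel$r2, tolerance = 1e-12)
  expect_equal(back$pos, panel$pos)
})
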