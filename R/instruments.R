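# Instrument selection: genome-wide significance filter, greedy LD clumping
# (univariable and joint across exposures), and instrument-strength metrics.

#' Clumping configuration
#'
#' Thresholds for instrument selection: genome-wide significance cutoff,
#' pairwise LD cutoff, and physical window.
#'
#' @param p_threshold significance cutoff; default `5e-8`.
#' @param r2_threshold squared-correlation cutoff above which two variants are
#'   considered dependent; default `0.001`.
#' @param window_kb physical clumping window in kilobases; default `1000`.
#' @return an object of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 1000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_config")
}

#' LD reference panel of pairwise squared correlations
#'
#' @param rsids character vector of variant identifiers.
#' @param r2 symmetric matrix of pairwise squared correlations in `[0, 1]`
#'   with unit diagonal, rows/columns ordered as `rsids`.
#' @param chrom,pos chromosome label and 1-based position per variant.
#' @return an object of class `ld_panel`.
#' @export
ld_panel <- function(rsids, r2, chrom, pos) {
  rsids <- as.character(rsids)
  r2 <- as.matrix(r2)
  stopifnot(length(rsids) == nrow(r2), nrow(r2) == ncol(r2),
            length(chrom) == length(rsids), length(pos) == length(rsids))
  if (anyDuplicated(rsids)) stop("duplicated rsids in LD panel", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("r2 values outside [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix not symmetric",
                                        call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1",
                                          call. = FALSE)
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2, chrom = as.character(chrom),
                 pos = as.numeric(pos)), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("LD panel: ", length(x$rsids), " variants\n", sep = "")
  invisible(x)
}

#' Read an LD panel from a pairwise-r2 triple file and a position sidecar
#'
#' @param r2_path tab-delimited file with header `rsid_a  rsid_b  r2`; pairs
#'   not listed are taken as r2 = 0, the diagonal is implied.
#' @param pos_path tab-delimited sidecar with header `rsid  chrom  pos`
#'   listing every panel variant.
#' @return an `ld_panel` object.
#' @export
read_ld_panel <- function(r2_path, pos_path) {
  pos <- utils::read.table(pos_path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
  pairs <- utils::read.table(r2_path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "numeric"))
  n <- nrow(pos)
  r2 <- diag(1, n)
  ia <- match(pairs$rsid_a, pos$rsid)
  ib <- match(pairs$rsid_b, pos$rsid)
  if (anyNA(ia) || anyNA(ib)) {
    stop("pair file references variants absent from the position sidecar",
         call. = FALSE)
  }
  r2[cbind(ia, ib)] <- pairs$r2
  r2[cbind(ib, ia)] <- pairs$r2
  ld_panel(pos$rsid, r2, pos$chrom, pos$pos)
}

#' Write an LD panel as a pairwise-r2 triple file plus position sidecar
#'
#' Only the upper triangle with r2 > 0 is written.
#'
#' @param panel an `ld_panel` object.
#' @param r2_path,pos_path output paths.
#' @return `r2_path`, invisibly.
#' @export
write_ld_panel <- function(panel, r2_path, pos_path) {
  stopifnot(inherits(panel, "ld_panel"))
  idx <- which(upper.tri(panel$r2) & panel$r2 > 0, arr.ind = TRUE)
  pairs <- data.frame(rsid_a = panel$rsids[idx[, 1L]],
                      rsid_b = panel$rsids[idx[, 2L]],
                      r2 = panel$r2[idx])
  utils::write.table(pairs, r2_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(rsid = panel$rsids, chrom = panel$chrom,
                                pos = panel$pos),
                     pos_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(r2_path)
}

#' Filter variants at a significance threshold
#'
#' @param stats a `gwas_sumstats` object.
#' @param p_threshold retain variants with `pvalue < p_threshold`;
#'   default genome-wide significance `5e-8`.
#' @return a `gwas_sumstats` object with the retained subset, input order
#'   preserved. Warns (does not error) when nothing passes.
#' @export
filter_genome_wide <- function(stats, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "gwas_sumstats"), p_threshold > 0,
            p_threshold <= 1)
  keep <- stats$data$pvalue < p_threshold
  if (!any(keep)) {
    warning("no variants pass p < ", format(p_threshold), " for trait '",
            stats$trait, "'", call. = FALSE)
  }
  out <- stats
  out$data <- stats$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value (ties
#' broken by lexicographic rsID) as an index variant and removes every
#' remaining variant on the same chromosome within `window_kb` whose squared
#' correlation with it exceeds `r2_threshold`. Candidates absent from the
#' panel are dropped with a message.
#'
#' @param candidates a `gwas_sumstats` object (typically genome-wide
#'   significant variants).
#' @param panel an `ld_panel` covering the candidates.
#' @param config a [clump_config()].
#' @return a `gwas_sumstats` object containing the index variants, ordered by
#'   selection (ascending p-value).
#' @export
ld_clump <- function(candidates, panel, config = clump_config()) {
  stopifnot(inherits(candidates, "gwas_sumstats"), inherits(panel, "ld_panel"),
            inherits(config, "clump_config"))
  d <- candidates$data
  in_panel <- d$rsid %in% panel$rsids
  if (!all(in_panel)) {
    message(sum(!in_panel), " candidate variant(s) absent from LD panel, ",
            "dropped")
    d <- d[in_panel, , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    out <- candidates
    out$data <- d
    return(out)
  }
  ord <- order(d$pvalue, d$rsid)
  d <- d[ord, , drop = FALSE]
  window_bp <- config$window_kb * 1000
  alive <- rep(TRUE, nrow(d))
  index <- logical(nrow(d))
  r2sub <- panel$r2[d$rsid, d$rsid, drop = FALSE]
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    prune <- alive &
      d$chrom == d$chrom[i] &
      abs(d$pos - d$pos[i]) <= window_bp &
      r2sub[i, ] > config$r2_threshold
    alive[prune] <- FALSE
  }
  out <- candidates
  out$data <- d[index, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Joint clumping across several exposures
#'
#' Pools the union of per-exposure genome-wide significant variants, assigns
#' each pooled variant the minimum p-value over the exposures in which it is
#' significant, and applies [ld_clump()] to that combined ranking. This is the
#' instrument-selection rule for multivariable MR, where a variant may proxy
#' either exposure.
#'
#' @param exposures list of two or more `gwas_sumstats` objects.
#' @param panel an `ld_panel`.
#' @param config a [clump_config()]; `p_threshold` is applied per exposure
#'   before pooling.
#' @return a `gwas_sumstats` object of index variants; each record carries the
#'   coordinates/alleles of the exposure achieving its minimum p-value.
#' @export
clump_joint <- function(exposures, panel, config = clump_config()) {
  stopifnot(is.list(exposures), length(exposures) >= 2L)
  sig <- lapply(exposures, function(e) {
    suppressWarnings(filter_genome_wide(e, config$p_threshold))$data
  })
  pooled <- do.call(rbind, sig)
  if (nrow(pooled) == 0L) {
    warning("no variants pass the significance threshold in any exposure",
            call. = FALSE)
    out <- exposures[[1L]]
    out$data <- pooled
    return(out)
  }
  pooled <- pooled[order(pooled$pvalue, pooled$rsid), , drop = FALSE]
  pooled <- pooled[!duplicated(pooled$rsid), , drop = FALSE]
  combined <- gwas_sumstats(pooled, trait = paste(
    vapply(exposures, function(e) e$trait, character(1)), collapse = "+"))
  ld_clump(combined, panel, config)
}

#' Instrument-strength diagnostics: variance explained and F statistics
#'
#' Per-variant variance explained uses the standardized-trait approximation
#' `R2_j = 2 * eaf_j * (1 - eaf_j) * beta_j^2`; variants with missing
#' frequency are excluded from the total R2 and counted. Per-variant
#' `F_j = (beta_j / se_j)^2`; the overall F statistic is
#' `R2 (n - k - 1) / ((1 - R2) k)`.
#'
#' @param instruments a `gwas_sumstats` object of selected instruments.
#' @param n exposure sample size; defaults to the object's `sample_n`.
#' @return An object of class `instrument_strength`: list with `r2_total`,
#'   `f_per_snp` (named by rsid), `f_overall`, `k`, `n`, and
#'   `n_missing_eaf`.
#' @export
instrument_strength <- function(instruments, n = instruments$sample_n) {
  stopifnot(inherits(instruments, "gwas_sumstats"))
  d <- instruments$data
  k <- nrow(d)
  if (k < 1L) stop("no instruments supplied", call. = FALSE)
  has_eaf <- !is.na(d$eaf)
  r2_per <- 2 * d$eaf[has_eaf] * (1 - d$eaf[has_eaf]) * d$beta[has_eaf]^2
  r2_total <- sum(r2_per)
  f_per <- stats::setNames((d$beta / d$se)^2, d$rsid)
  if (n <= k + 1) {
    stop("overall F undefined: sample size n = ", n,
         " must exceed k + 1 = ", k + 1, call. = FALSE)
  }
  f_overall <- r2_total * (n - k - 1) / ((1 - r2_total) * k)
  structure(list(r2_total = r2_total, f_per_snp = f_per,
                 f_overall = f_overall, k = k, n = n,
                 n_missing_eaf = sum(!has_eaf)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf(
    "Instrument strength: k = %d, R2 = %.4f (%.1f%%), overall F = %.1f\n",
    x$k, x$r2_total, 100 * x$r2_total, x$f_overall))
  cat(sprintf("  per-SNP F: min %.1f, median %.1f\n",
              min(x$f_per_snp), stats::median(x$f_per_snp)))
  if (x$n_missing_eaf > 0) {
    cat("  ", x$n_missing_eaf, " variant(s) missing eaf excluded from R2\n",
        sep = "")
  }
  invisible(x)
}

#' Export an instrument table (supplementary-material shape)
#'
#' Writes one row per instrument: rsid, effect/other allele, eaf, beta, se,
#' p-value, and per-variant F statistic, tab-delimited.
#'
#' @param instruments a `gwas_sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instrument_table <- function(instruments, path) {
  d <- instruments$data
  out <- data.frame(rsid = d$rsid, effect_allele = d$effect_allele,
                    other_allele = d$other_allele, eaf = d$eaf,
                    beta = d$beta, se = d$se, pvalue = d$pvalue,
                    F = (d$beta / d$se)^2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
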