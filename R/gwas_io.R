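# GWAS summary-statistics data model, file I/O, and allele harmonization.

CANONICAL_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pvalue", "n")
REQUIRED_COLUMNS <- setdiff(CANONICAL_COLUMNS, "eaf")

#' Construct a validated GWAS summary-statistics object
#'
#' Container for per-variant association results of one trait in one study
#' sample. Each row is a variant with its rsID, genomic coordinates (1-based),
#' effect and other allele, effect-allele frequency (optional), additive
#' per-allele effect (log odds ratio for binary traits), standard error,
#' p-value, and per-variant sample size.
#'
#' Rows violating the record invariants (non-positive SE, identical alleles,
#' frequency outside (0,1), p-value outside (0,1], non-positive position or
#' sample size, duplicated rsID) are dropped; the drop tally is attached as a
#' load report retrievable with [load_report()].
#'
#' @param data data.frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf` (optional, `NA` allowed), `beta`, `se`, `pvalue`,
#'   `n`.
#' @param trait character label for the trait.
#' @param sample_n study sample size; defaults to the maximum per-variant `n`.
#' @return An object of class `gwas_sumstats`: a list with elements `trait`,
#'   `sample_n`, and `data` (the validated data.frame).
#' @export
gwas_sumstats <- function(data, trait, sample_n = NULL) {
  stopifnot(is.data.frame(data), is.character(trait), length(trait) == 1L)
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, CANONICAL_COLUMNS]
  data$rsid <- as.character(data$rsid)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    data[[col]] <- as.numeric(data[[col]])
  }

  reasons <- character(0)
  bad <- rep(FALSE, nrow(data))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    new <- cond & !bad
    if (any(new)) reasons <<- c(reasons, rep(why, sum(new)))
    bad <<- bad | cond
  }
  valid_allele <- function(a) a %in% c("A", "C", "G", "T")
  flag(!valid_allele(data$effect_allele) | !valid_allele(data$other_allele),
       "invalid allele")
  flag(data$effect_allele == data$other_allele, "identical alleles")
  flag(is.na(data$se) | data$se <= 0, "non-positive se")
  flag(is.na(data$beta), "missing beta")
  flag(is.na(data$pvalue) | data$pvalue <= 0 | data$pvalue > 1,
       "p-value outside (0,1]")
  flag(is.na(data$pos) | data$pos < 1, "invalid position")
  flag(is.na(data$n) | data$n <= 0, "invalid sample size")
  flag(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1),
       "eaf outside (0,1)")
  flag(is.na(data$rsid) | data$rsid == "" | duplicated(data$rsid),
       "missing or duplicated rsid")

  n_in <- nrow(data)
  data <- data[!bad, , drop = FALSE]
  rownames(data) <- NULL
  if (nrow(data) == 0L) {
    stop("no valid rows for trait '", trait, "' (", n_in, " read, all dropped)",
         call. = FALSE)
  }
  if (is.null(sample_n)) sample_n <- max(data$n)
  obj <- structure(list(trait = trait, sample_n = sample_n, data = data),
                   class = "gwas_sumstats")
  attr(obj, "load_report") <- list(
    trait = trait, n_read = n_in, n_valid = nrow(data),
    n_dropped = n_in - nrow(data),
    drop_reasons = as.list(table(reasons)))
  obj
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait, "\n",
      "  variants: ", nrow(x$data), "; sample size: ", x$sample_n, "\n",
      sep = "")
  invisible(x)
}

#' Retrieve the load/validation report attached to a summary-stats object
#'
#' @param x a `gwas_sumstats` object.
#' @return list with `n_read`, `n_valid`, `n_dropped` and per-reason counts.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Number of variants in a summary-statistics object
#' @param x a `gwas_sumstats` object.
#' @export
n_variants <- function(x) nrow(x$data)

#' Read GWAS summary statistics from a delimited text file
#'
#' The canonical dialect is tab-delimited with a header row and `.` for
#' missing values; comma-delimited files are detected automatically. Files
#' with non-canonical headers are supported through `column_map`.
#'
#' @param path path to the file.
#' @param trait trait label.
#' @param column_map optional named character vector mapping canonical field
#'   names to the file's header names, e.g. `c(rsid = "SNP", pvalue = "P")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param sample_n optional study sample size override.
#' @return a validated [gwas_sumstats()] object with a load report attached.
#' @export
read_summary_stats <- function(path, trait, column_map = NULL,
                               sample_n = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, na.strings = ".",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  wanted <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), CANONICAL_COLUMNS)
    if (length(unknown) > 0L) {
      stop("column_map names unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    wanted[names(column_map)] <- column_map
  }
  required <- wanted[REQUIRED_COLUMNS]
  missing_cols <- required[!required %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("required column(s) not found in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", names(missing_cols),
                       missing_cols), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(rsid = raw[[wanted["rsid"]]], stringsAsFactors = FALSE)
  for (fld in setdiff(CANONICAL_COLUMNS, "rsid")) {
    src <- wanted[[fld]]
    out[[fld]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  gwas_sumstats(out, trait = trait, sample_n = sample_n)
}

#' Write GWAS summary statistics in the canonical dialect
#'
#' Tab-delimited, header row, `.` for missing values. Reading a canonical file
#' and writing it again reproduces it byte-identically.
#'
#' @param x a `gwas_sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "gwas_sumstats"))
  d <- x$data
  fmt <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "." else format(z, scientific = NA, trim = TRUE,
                                    digits = 15)
    }, character(1))
    out
  }
  lines <- c(paste(CANONICAL_COLUMNS, collapse = "\t"),
             do.call(paste, c(lapply(CANONICAL_COLUMNS, function(col) {
               if (is.numeric(d[[col]])) fmt(d[[col]]) else as.character(d[[col]])
             }), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
complement_allele <- function(a) unname(DNA_COMPLEMENT[a])
is_palindromic <- function(ea, oa) complement_allele(ea) == oa

# Resolve one outcome record against the exposure orientation.
# Returns "keep", "flip", or "drop:<reason>".
resolve_orientation <- function(ea_x, oa_x, ea_y, oa_y,
                                eaf_x, eaf_y, window) {
  if (is_palindromic(ea_x, oa_x)) {
    if (!is_palindromic(ea_y, oa_y)) return("drop:irreconcilable")
    # Strand is ambiguous for A/T and C/G pairs: resolve by allele-frequency
    # concordance, or drop near 0.5 where frequency carries no information.
    if (is.na(eaf_x) || is.na(eaf_y)) return("drop:palindromic")
    if (abs(eaf_x - 0.5) <= window || abs(eaf_y - 0.5) <= window) {
      return("drop:palindromic")
    }
    letter_flip <- (ea_y == oa_x && oa_y == ea_x)
    if (!letter_flip && !(ea_y == ea_x && oa_y == oa_x)) {
      return("drop:irreconcilable")
    }
    eaf_aligned <- if (letter_flip) 1 - eaf_y else eaf_y
    freq_flip <- (eaf_x - 0.5) * (eaf_aligned - 0.5) < 0
    return(if (xor(letter_flip, freq_flip)) "flip" else "keep")
  }
  if (ea_y == ea_x && oa_y == oa_x) return("keep")
  if (ea_y == oa_x && oa_y == ea_x) return("flip")
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  if (cea == ea_x && coa == oa_x) return("keep")
  if (cea == oa_x && coa == ea_x) return("flip")
  "drop:irreconcilable"
}

#' Harmonize exposure and outcome summary statistics to one allele orientation
#'
#' Intersects the two studies on rsID and re-orients every outcome record to
#' the exposure's effect allele: records with swapped alleles have their beta
#' sign flipped and frequency reflected; records reported on the opposite
#' strand are complemented before comparison. Palindromic variants (A/T or
#' C/G) cannot be strand-resolved from the alleles, so they are resolved by
#' allele-frequency concordance and dropped when the effect-allele frequency
#' lies within `palindrome_eaf_window` of 0.5 in either study (or is missing).
#'
#' @param exposure,outcome `gwas_sumstats` objects.
#' @param palindrome_eaf_window half-width of the frequency band around 0.5
#'   inside which palindromic variants are dropped; default 0.08.
#' @return An object of class `harmonized_data`: list with `rsids`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `n_dropped_palindromic`, `orientation_flips`,
#'   `drop_log` (per-variant reasons), and trait labels.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "gwas_sumstats"),
            inherits(outcome, "gwas_sumstats"),
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  shared <- intersect(exposure$data$rsid, outcome$data$rsid)
  if (length(shared) == 0L) {
    stop("no shared variants between '", exposure$trait, "' and '",
         outcome$trait, "'", call. = FALSE)
  }
  ex <- exposure$data[match(shared, exposure$data$rsid), ]
  oy <- outcome$data[match(shared, outcome$data$rsid), ]

  action <- vapply(seq_along(shared), function(i) {
    resolve_orientation(ex$effect_allele[i], ex$other_allele[i],
                        oy$effect_allele[i], oy$other_allele[i],
                        ex$eaf[i], oy$eaf[i], palindrome_eaf_window)
  }, character(1))

  keep <- !startsWith(action, "drop")
  flip <- action == "flip"
  beta_y <- ifelse(flip, -oy$beta, oy$beta)

  drop_log <- data.frame(rsid = shared[!keep],
                         reason = sub("^drop:", "", action[!keep]),
                         stringsAsFactors = FALSE)
  structure(list(
    rsids = shared[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_y[keep],
    se_outcome = oy$se[keep],
    eaf_exposure = ex$eaf[keep],
    n_dropped_palindromic = sum(action == "drop:palindromic"),
    orientation_flips = sum(flip),
    drop_log = drop_log,
    exposure_trait = exposure$trait,
    outcome_trait = outcome$trait,
    n_exposure = exposure$sample_n,
    n_outcome = outcome$sample_n
  ), class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat("Harmonized exposure-outcome data: ", x$exposure_trait, " -> ",
      x$outcome_trait, "\n  variants: ", length(x$rsids),
      "; flips: ", x$orientation_flips,
      "; palindromic drops: ", x$n_dropped_palindromic, "\n", sep = "")
  invisible(x)
}

#' Number of variants in a harmonized dataset
#' @param x a `harmonized_data` or `mv_harmonized_data` object.
#' @export
n_snps <- function(x) length(x$rsids)

#' Construct harmonized data directly from effect vectors
#'
#' Convenience constructor for already-aligned effect estimates (all vectors
#' on a common effect-allele orientation), used by simulation studies and
#' tests that bypass file-level harmonization.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome numeric vectors of
#'   equal length; SEs strictly positive.
#' @param rsids optional variant identifiers (defaults to `snp_1`, ...).
#' @param eaf_exposure optional effect-allele frequencies.
#' @return a `harmonized_data` object.
#' @export
harmonized_data <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome, rsids = NULL, eaf_exposure = NULL) {
  j <- length(beta_exposure)
  stopifnot(length(se_exposure) == j, length(beta_outcome) == j,
            length(se_outcome) == j, all(se_exposure > 0),
            all(se_outcome > 0))
  if (is.null(rsids)) rsids <- sprintf("snp_%d", seq_len(j))
  if (is.null(eaf_exposure)) eaf_exposure <- rep(NA_real_, j)
  structure(list(rsids = as.character(rsids),
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 eaf_exposure = as.numeric(eaf_exposure),
                 n_dropped_palindromic = 0L, orientation_flips = 0L,
                 drop_log = data.frame(rsid = character(0),
                                       reason = character(0)),
                 exposure_trait = "exposure", outcome_trait = "outcome",
                 n_exposure = NA_real_, n_outcome = NA_real_),
            class = "harmonized_data")
}

#' Harmonize several exposures and one outcome to a common orientation
#'
#' Intersects all studies on rsID and anchors the allele orientation on the
#' first exposure; every other study is re-oriented against that anchor with
#' the same swap/strand/palindrome rules as [harmonize()]. A variant dropped
#' against any study is dropped everywhere.
#'
#' @param exposures list of two or more `gwas_sumstats` objects; the first
#'   one defines the orientation anchor.
#' @param outcome a `gwas_sumstats` object.
#' @param palindrome_eaf_window as in [harmonize()].
#' @return An object of class `mv_harmonized_data`: list with `rsids`,
#'   `beta_exposures` and `se_exposures` (J x K matrices), `beta_outcome`,
#'   `se_outcome`, `exposure_labels`, and drop counters.
#' @export
harmonize_multi <- function(exposures, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 2L,
            inherits(outcome, "gwas_sumstats"))
  for (e in exposures) stopifnot(inherits(e, "gwas_sumstats"))
  k <- length(exposures)
  anchor <- exposures[[1L]]
  shared <- Reduce(intersect, c(lapply(exposures, function(e) e$data$rsid),
                                list(outcome$data$rsid)))
  if (length(shared) == 0L) stop("no variants shared by all studies",
                                 call. = FALSE)
  ax <- anchor$data[match(shared, anchor$data$rsid), ]

  align_study <- function(study) {
    sd <- study$data[match(shared, study$data$rsid), ]
    action <- vapply(seq_along(shared), function(i) {
      resolve_orientation(ax$effect_allele[i], ax$other_allele[i],
                          sd$effect_allele[i], sd$other_allele[i],
                          ax$eaf[i], sd$eaf[i], palindrome_eaf_window)
    }, character(1))
    list(beta = ifelse(action == "flip", -sd$beta, sd$beta),
         se = sd$se, action = action)
  }

  aligned <- lapply(c(exposures[-1L], list(outcome)), align_study)
  actions <- do.call(cbind, lapply(aligned, `[[`, "action"))
  keep <- apply(actions, 1L, function(a) !any(startsWith(a, "drop")))
  if (!any(keep)) stop("all shared variants dropped during harmonization",
                       call. = FALSE)
  beta_mat <- cbind(ax$beta,
                    do.call(cbind, lapply(aligned[-k], `[[`, "beta")))[keep, ,
                                                                      drop = FALSE]
  se_mat <- cbind(ax$se,
                  do.call(cbind, lapply(aligned[-k], `[[`, "se")))[keep, ,
                                                                  drop = FALSE]
  labels <- vapply(exposures, function(e) e$trait, character(1))
  colnames(beta_mat) <- labels
  colnames(se_mat) <- labels
  out_beta <- aligned[[k]]$beta[keep]
  out_se <- aligned[[k]]$se[keep]
  structure(list(
    rsids = shared[keep],
    beta_exposures = beta_mat,
    se_exposures = se_mat,
    beta_outcome = out_beta,
    se_outcome = out_se,
    exposure_labels = labels,
    eaf_anchor = ax$eaf[keep],
    n_dropped_palindromic = sum(actions == "drop:palindromic"),
    orientation_flips = sum(actions == "flip"),
    outcome_trait = outcome$trait,
    n_outcome = outcome$sample_n
  ), class = "mv_harmonized_data")
}

#' Construct multivariable harmonized data from effect matrices
#'
#' @param beta_exposures,se_exposures numeric J x K matrices.
#' @param beta_outcome,se_outcome numeric vectors of length J.
#' @param rsids optional identifiers; `exposure_labels` optional K labels.
#' @param exposure_labels optional labels for the K exposures.
#' @return an `mv_harmonized_data` object.
#' @export
mv_harmonized_data <- function(beta_exposures, se_exposures, beta_outcome,
                               se_outcome, rsids = NULL,
                               exposure_labels = NULL) {
  beta_exposures <- as.matrix(beta_exposures)
  se_exposures <- as.matrix(se_exposures)
  j <- nrow(beta_exposures); k <- ncol(beta_exposures)
  stopifnot(identical(dim(se_exposures), dim(beta_exposures)),
            length(beta_outcome) == j, length(se_outcome) == j,
            all(se_exposures > 0), all(se_outcome > 0), k >= 1L)
  if (is.null(rsids)) rsids <- sprintf("snp_%d", seq_len(j))
  if (is.null(exposure_labels)) {
    exposure_labels <- colnames(beta_exposures)
    if (is.null(exposure_labels)) {
      exposure_labels <- sprintf("exposure_%d", seq_len(k))
    }
  }
  colnames(beta_exposures) <- exposure_labels
  colnames(se_exposures) <- exposure_labels
  structure(list(rsids = as.character(rsids),
                 beta_exposures = beta_exposures,
                 se_exposures = se_exposures,
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 exposure_labels = exposure_labels,
                 eaf_anchor = rep(NA_real_, j),
                 n_dropped_palindromic = 0L, orientation_flips = 0L,
                 outcome_trait = "outcome", n_outcome = NA_real_),
            class = "mv_harmonized_data")
}

#' @export
print.mv_harmonized_data <- function(x, ...) {
  cat("Multivariable harmonized data: ",
      paste(x$exposure_labels, collapse = " + "), " -> ", x$outcome_trait,
      "\n  variants: ", length(x$rsids), "\n", sep = "")
  invisible(x)
}
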