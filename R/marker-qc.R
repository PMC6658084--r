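#' Minor-allele-frequency threshold from sample size
#'
#' Computes the MAF exclusion threshold `1 / sqrt(2 * n_clones)` used when
#' filtering SNP markers ahead of genomic analyses. At the typical panel size
#' of a few hundred clones this keeps only alleles seen often enough for their
#' frequency (and hence their contribution to the genomic relationship matrix)
#' to be estimated with some stability; e.g. 290 clones give a threshold of
#' 0.0415.
#'
#' @param n_clones Number of genotyped clones (positive integer).
#' @return A single numeric threshold in (0, 0.5].
#' @export
#' @examples
#' maf_threshold(290) # ~0.0415
maf_threshold <- function(n_clones) {
  if (length(n_clones) != 1 || is.na(n_clones) || n_clones < 1) {
    stop_stagegs("`n_clones` must be a single integer >= 1.",
      class = "stagegs_config_error"
    )
  }
  1 / sqrt(2 * n_clones)
}

#' Per-marker allele frequency from dosages
#'
#' Frequency of the counted (alternative) allele, `p_i`, computed as half the
#' mean dosage over non-missing entries. Markers with no non-missing entries
#' get `NA`.
#'
#' @param geno Clones x markers dosage matrix with entries in {0, 1, 2, NA}.
#' @return Named numeric vector of frequencies, one per marker column.
#' @export
allele_freq <- function(geno) {
  check_dosage(geno)
  colMeans(geno, na.rm = TRUE) / 2
}

# internal: validate a dosage matrix
check_dosage <- function(geno) {
  if (!is.matrix(geno) || !is.numeric(geno)) {
    stop_stagegs("Genotypes must be a numeric clones x markers matrix.")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop_stagegs("Dosages must lie in [0, 2] (codes 0/1/2, NA = missing).")
  }
  if (anyDuplicated(rownames(geno)) || anyDuplicated(colnames(geno))) {
    stop_stagegs("Duplicated clone or marker IDs in the dosage matrix.")
  }
  invisible(geno)
}

#' Marker quality control: call rate then minor allele frequency
#'
#' Removes markers in two passes, mirroring the usual GBS pipeline order:
#' first markers whose non-missing fraction falls below `call_rate_min`, then
#' markers whose minor allele frequency `min(p, 1 - p)` (computed over the
#' non-missing entries) falls below `maf_min`. Retained markers keep their
#' input order.
#'
#' @param geno Clones x markers dosage matrix (0/1/2, NA missing).
#' @param call_rate_min Minimum non-missing fraction per marker; default 0.90.
#' @param maf_min Minimum minor allele frequency. The default `NULL` uses the
#'   sample-size rule [maf_threshold()] with `N = nrow(geno)`.
#' @return A list of class `qc_result` with elements `genotypes` (the filtered
#'   matrix) and `report`, a one-row tibble with columns `n_input`,
#'   `n_removed_callrate`, `n_removed_maf`, `n_retained`, `call_rate_min`,
#'   `maf_min`.
#' @export
apply_qc <- function(geno, call_rate_min = 0.90, maf_min = NULL) {
  check_dosage(geno)
  if (is.null(maf_min)) maf_min <- maf_threshold(nrow(geno))
  if (call_rate_min < 0 || call_rate_min > 1 || maf_min < 0 || maf_min > 1) {
    stop_stagegs("QC thresholds must lie in [0, 1].",
      class = "stagegs_config_error"
    )
  }
  n_input <- ncol(geno)
  call_rate <- colMeans(!is.na(geno))
  drop_cr <- call_rate < call_rate_min
  kept <- geno[, !drop_cr, drop = FALSE]

  p <- allele_freq(kept)
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0 # an all-missing column that survived call rate
  drop_maf <- maf < maf_min
  out <- kept[, !drop_maf, drop = FALSE]

  if (ncol(out) == 0) {
    binding <- if (sum(drop_cr) >= sum(drop_maf)) "call rate" else "MAF"
    stop_stagegs(
      paste0(
        "All ", n_input, " markers removed by QC (binding threshold: ",
        binding, ")."
      ),
      class = "stagegs_qc_error"
    )
  }
  report <- tibble::tibble(
    n_input = n_input,
    n_removed_callrate = sum(drop_cr),
    n_removed_maf = sum(drop_maf),
    n_retained = ncol(out),
    call_rate_min = call_rate_min,
    maf_min = maf_min
  )
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(
    "Marker QC: ", r$n_input, " markers in; removed ",
    r$n_removed_callrate, " (call rate < ", r$call_rate_min, "), ",
    r$n_removed_maf, " (MAF < ", signif(r$maf_min, 4), "); retained ",
    r$n_retained, ".\n",
    sep = ""
  )
  invisible(x)
}

#' Impute missing dosages with the heterozygote
#'
#' Replaces every missing entry by dosage 1 (the heterozygote), the imputation
#' used for GBS panels where missingness is low and a neutral fill keeps the
#' allele-frequency centering of the genomic relationship matrix unbiased
#' toward either homozygote.
#'
#' @param geno Clones x markers dosage matrix (0/1/2, NA missing).
#' @return The same matrix with all `NA` entries replaced by 1.
#' @export
impute_missing <- function(geno) {
  check_dosage(geno)
  if (anyNA(geno)) geno[is.na(geno)] <- 1
  geno
}
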