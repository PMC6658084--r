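#' Backsolve SNP effects from genomic breeding values
#'
#' Recovers per-marker allele-substitution effects from GBLUP breeding
#' values via `m = Mc' (Mc Mc')^+ a`, using the symmetric pseudo-inverse so
#' rank-deficient `Mc Mc'` is handled. `Mc %*% m` is the projection of `a`
#' onto the column space of the centered marker matrix, which equals `a`
#' exactly for GBLUP solutions whose G was built from the same markers.
#'
#' @param Mc Column-centered clones x markers matrix ([center_markers()]).
#' @param a_hat Named (or Mc-row-aligned) numeric vector of genomic breeding
#'   values.
#' @return Tibble with columns `marker`, `effect`, one row per marker.
#' @export
backsolve_snp_effects <- function(Mc, a_hat) {
  if (!is.null(names(a_hat)) && !is.null(rownames(Mc))) {
    if (!all(rownames(Mc) %in% names(a_hat))) {
      stop_stagegs("`a_hat` does not cover all clones in `Mc`.")
    }
    a_hat <- a_hat[rownames(Mc)]
  }
  if (length(a_hat) != nrow(Mc)) {
    stop_stagegs("`a_hat` length must equal nrow(Mc).")
  }
  MMt <- tcrossprod(Mc)
  m <- as.numeric(crossprod(Mc, psolve_sym(MMt) %*% a_hat))
  tibble::tibble(
    marker = colnames(Mc) %||% paste0("M", seq_len(ncol(Mc))),
    effect = m
  )
}

#' Default selection-index weights
#'
#' Empirical economic weights for the five cassava traits: fresh root yield,
#' dry matter content and dry yield weighted 10, fresh shoot yield 5 and
#' harvest index 3.
#'
#' @return Named numeric vector of weights.
#' @export
default_index_weights <- function() {
  c(FRY = 10, DMC = 10, DY = 10, FSY = 5, HI = 3)
}

#' Empirical selection index over per-trait breeding values
#'
#' Weighted sum of (G)EBVs across traits, in original trait units (no
#' standardization unless `standardize = TRUE`). Clones missing any weighted
#' trait are excluded with a warning.
#'
#' @param bv_by_trait Either a long tibble (`clone`, `trait`, `bv`) — e.g.
#'   stacked [tidy.gs_fit()] outputs — or a wide data frame with a `clone`
#'   column and one column per trait.
#' @param weights Named weights; default [default_index_weights()].
#' @param standardize Scale each trait's breeding values to unit variance
#'   before weighting (off by default).
#' @return Tibble `clone`, `si`, sorted by decreasing index value.
#' @export
selection_index <- function(bv_by_trait, weights = default_index_weights(),
                            standardize = FALSE) {
  if (length(weights) == 0 || all(weights == 0) || any(!is.finite(weights))) {
    stop_stagegs("`weights` must be finite with at least one nonzero entry.")
  }
  bv <- as_tibble(bv_by_trait)
  if (all(c("trait", "bv") %in% names(bv))) {
    bv <- tidyr::pivot_wider(
      dplyr::select(bv, "clone", "trait", "bv"),
      names_from = "trait", values_from = "bv"
    )
  }
  missing_traits <- setdiff(names(weights), names(bv))
  if (length(missing_traits)) {
    stop_stagegs(paste0(
      "Traits absent from `bv_by_trait`: ",
      paste(missing_traits, collapse = ", ")
    ))
  }
  vals <- as.matrix(bv[names(weights)])
  complete <- stats::complete.cases(vals)
  if (!any(complete)) {
    stop_stagegs("No clones with complete breeding values for all index traits.")
  }
  if (any(!complete)) {
    rlang::warn(paste0(
      sum(!complete), " clone(s) missing a trait excluded from the index."
    ))
  }
  vals <- vals[complete, , drop = FALSE]
  if (standardize) vals <- scale(vals)
  tibble::tibble(
    clone = bv$clone[complete],
    si = as.numeric(vals %*% weights)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$si))
}

#' Select the top fraction of clones and estimate the genetic gain
#'
#' Selects the `ceiling(fraction * n)` clones with the highest values (ties
#' broken deterministically by clone ID) and reports the expected genetic
#' gain as the mean selected breeding-value deviation expressed as a percent
#' of the trait mean.
#'
#' @param values Named numeric vector (names = clone IDs) of breeding values,
#'   interpreted as deviations from the population mean.
#' @param trait_mean Phenotypic trait mean used as the gain denominator
#'   (must be > 0).
#' @param fraction Selected fraction in (0, 1]; default 0.10.
#' @return List with `selected` (clone IDs, best first) and `gain_percent`.
#' @export
top_fraction_gain <- function(values, trait_mean, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) {
    stop_stagegs("`fraction` must lie in (0, 1].")
  }
  if (!is.finite(trait_mean) || trait_mean <= 0) {
    stop_stagegs("`trait_mean` must be > 0.")
  }
  if (is.null(names(values))) {
    names(values) <- paste0("clone", seq_along(values))
  }
  n_sel <- ceiling(fraction * length(values))
  ord <- order(-values, names(values))
  selected <- names(values)[ord][seq_len(n_sel)]
  gain <- 100 * mean(values[selected]) / trait_mean
  list(selected = selected, gain_percent = gain)
}

#' Coincidence between two clone rankings
#'
#' Overlap between two top-clone lists (e.g. the top 10% by one-stage GEBV
#' versus four-stage EBV), with the percent computed over the first list.
#' Optionally also reports the correlation between the two full
#' breeding-value vectors over their shared clones.
#'
#' @param list_a,list_b Character vectors of selected clone IDs.
#' @param values_a,values_b Optional named full breeding-value vectors from
#'   the two analyses, used for the correlation.
#' @return One-row tibble: `n_a`, `n_b`, `overlap`, `percent`, `correlation`.
#' @export
ranking_overlap <- function(list_a, list_b, values_a = NULL, values_b = NULL) {
  if (length(list_a) == 0 || length(list_b) == 0) {
    stop_stagegs("Ranking lists must be non-empty.")
  }
  if (length(list_a) != length(list_b)) {
    rlang::warn("Lists have unequal lengths; percent computed over the first list.")
  }
  ov <- length(intersect(list_a, list_b))
  correlation <- NA_real_
  if (!is.null(values_a) && !is.null(values_b)) {
    shared <- intersect(names(values_a), names(values_b))
    if (length(shared) >= 3) {
      correlation <- cor(values_a[shared], values_b[shared])
    }
  }
  tibble::tibble(
    n_a = length(list_a), n_b = length(list_b),
    overlap = ov, percent = 100 * ov / length(list_a),
    correlation = correlation
  )
}
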