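#' Fit the pedigree- or genomic-BLUP model for one trait
#'
#' Filters the long-format records to one trait, builds the genotype-by-
#' location structure and design matrices, estimates variance components by
#' AI-REML and returns breeding values. With a pedigree relationship matrix
#' the clone BLUPs are EBVs; with a genomic relationship matrix they are
#' GEBVs.
#'
#' @param records Long-format tibble: `clone`, `stage`, `location`, `year`,
#'   `block`, `rep`, `trait`, `value`. Records with missing `value` for the
#'   trait are dropped.
#' @param trait Trait name to fit.
#' @param K Relationship matrix (pedigree A or genomic G); its rownames
#'   define the clone universe, which may exceed the phenotyped clones —
#'   unphenotyped clones are predicted through kinship.
#' @param kind `"pedigree"` or `"genomic"` (labelling only; the model is the
#'   same).
#' @param interaction Include the genotype-by-location random effect
#'   (default `TRUE`).
#' @param blend Identity blend for `K` before inversion; `NULL` = automatic
#'   (0 when `K` is well conditioned, else 0.01).
#' @param ... Passed to [reml_fit()] (tolerances, `max_iter`, `init`).
#' @return A `gs_fit` object (extends `reml_fit`): adds `trait`, `kind`,
#'   `records` (the rows used, with fitted values and residuals) and
#'   `trait_mean`.
#' @export
fit_blup <- function(records, trait, K,
                     kind = c("pedigree", "genomic"),
                     interaction = TRUE, blend = NULL, ...) {
  kind <- match.arg(kind)
  records <- as_tibble(records)
  if (!all(c("trait", "value") %in% names(records))) {
    stop_stagegs("`records` must be long format with `trait` and `value` columns.")
  }
  rec <- dplyr::filter(records, .data$trait == !!trait, !is.na(.data$value))
  if (nrow(rec) == 0) {
    stop_stagegs(paste0("No non-missing records for trait ", trait, "."))
  }
  clones <- rownames(K)
  int <- if (interaction) expand_blockdiag(K, rec) else NULL
  design <- build_design(rec, clones, int)
  fit <- reml_fit(design, rec$value, K, K_L = int, blend = blend, ...)
  fit$trait <- trait
  fit$kind <- kind
  fit$trait_mean <- mean(rec$value)
  fit$records <- dplyr::mutate(rec,
    .fitted = fit$solutions$fitted,
    .resid = fit$solutions$residuals
  )
  class(fit) <- c("gs_fit", class(fit))
  fit
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(
    if (x$kind == "genomic") "Genomic" else "Pedigree",
    " BLUP fit for ", x$trait, "\n",
    sep = ""
  )
  NextMethod()
}

#' @rdname fit_blup
#' @param x A `gs_fit` object.
#' @return `tidy()`: a tibble of per-clone breeding values (`clone`, `bv`,
#'   `trait`, `kind`), EBVs for pedigree fits and GEBVs for genomic fits.
#' @method tidy gs_fit
#' @export
tidy.gs_fit <- function(x, ...) {
  tibble::tibble(
    clone = names(x$solutions$a),
    bv = unname(x$solutions$a),
    trait = x$trait,
    kind = x$kind
  )
}

#' @rdname fit_blup
#' @return `glance()`: a one-row tibble of variance components, ratios,
#'   log-likelihood and fit bookkeeping.
#' @method glance gs_fit
#' @export
glance.gs_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(trait = x$trait, kind = x$kind),
    x$vc,
    tibble::tibble(
      logLik = x$logLik, n_iterations = x$n_iterations,
      converged = x$converged, n_records = x$n,
      n_clones = x$n_clones
    )
  )
}

#' @rdname fit_blup
#' @return `augment()`: the records used in the fit with `.fitted` and
#'   `.resid` columns.
#' @method augment gs_fit
#' @export
augment.gs_fit <- function(x, ...) {
  x$records
}

#' Fit the restricted model without the clone genetic effect
#'
#' The reduced model `y = Xb + Z2 aL + e` used in the likelihood-ratio test
#' of the genotype effect: the genotype-by-location term is kept, the clone
#' main effect dropped. Implemented by promoting the interaction structure to
#' the single random effect of a one-term model.
#'
#' @inheritParams fit_blup
#' @return A `reml_fit` object (its `sigma2_a` slot holds the interaction
#'   variance; `sigma2_aL` is 0 by construction).
#' @export
fit_no_genotype <- function(records, trait, K, blend = NULL, ...) {
  records <- as_tibble(records)
  rec <- dplyr::filter(records, .data$trait == !!trait, !is.na(.data$value))
  int <- expand_blockdiag(K, rec)
  KL <- as.matrix(int)
  slots <- rownames(KL)
  rec2 <- dplyr::mutate(rec, clone = paste(.data$location, .data$clone, sep = ":"))
  design <- build_design(rec2, slots, interaction = NULL)
  reml_fit(design, rec2$value, KL, K_L = NULL, blend = blend, ...)
}
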