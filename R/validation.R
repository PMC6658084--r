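#' Random clone-level fold assignment
#'
#' Partitions clones uniformly at random into `k` folds whose sizes differ by
#' at most one. All records of a clone share its fold, so no clone leaks
#' across the training/validation split.
#'
#' @param clone_ids Character vector of clone IDs (no duplicates).
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Tibble with columns `clone`, `fold`.
#' @export
assign_folds <- function(clone_ids, k = 10, seed = 1L) {
  clone_ids <- sort(unique(as.character(clone_ids))) # order-independent
  if (k < 2) {
    stop_stagegs("`k` must be >= 2.", class = "stagegs_config_error")
  }
  if (k > length(clone_ids)) {
    stop_stagegs("`k` exceeds the number of clones.",
      class = "stagegs_config_error"
    )
  }
  set.seed(seed)
  perm <- sample(clone_ids)
  # cycling 1..k along a random permutation gives sizes differing by <= 1
  tibble::tibble(clone = perm, fold = rep(seq_len(k), length.out = length(perm))) %>%
    dplyr::arrange(.data$clone)
}

#' Pseudo-phenotypes: predicted genetic values plus mean residual
#'
#' For each phenotyped clone, the validation target used in cross-validation:
#' its predicted genetic value from the full-data fit plus the mean of its
#' residuals across all its records. This adjusts each clone's genetic value
#' back toward its own data, while staying fixed across folds.
#'
#' @param fit A [fit_blup()] result on the complete dataset.
#' @param records Records to average residuals over; defaults to the rows
#'   used in `fit`.
#' @return Tibble with columns `clone`, `pgv`, `pp` (clones with no record
#'   are excluded).
#' @export
pseudo_phenotypes <- function(fit, records = fit$records) {
  stopifnot(inherits(fit, "gs_fit"))
  if (!".resid" %in% names(records)) {
    stop_stagegs("`records` must carry `.resid` (use augment(fit)).")
  }
  records %>%
    dplyr::group_by(.data$clone) %>%
    dplyr::summarise(mean_resid = mean(.data$.resid), .groups = "drop") %>%
    dplyr::mutate(
      pgv = unname(fit$solutions$a[.data$clone]),
      pp = .data$pgv + .data$mean_resid
    ) %>%
    dplyr::select("clone", "pgv", "pp")
}

#' Predictive ability, accuracy and bias of predicted genetic values
#'
#' Predictive ability is the Pearson correlation between predicted genetic
#' values and pseudo-phenotypes; accuracy divides it by the square root of
#' the trait heritability; bias is one minus the slope of the regression of
#' pseudo-phenotypes on predicted genetic values (slope > 1, i.e. negative
#' bias, means the predictions under-dispersed the true differences).
#'
#' @param pgv,pp Equal-length numeric vectors (>= 3 values).
#' @param h2 Trait heritability in (0, 1].
#' @return One-row tibble: `pa`, `accuracy`, `bias`, `n`.
#' @export
prediction_metrics <- function(pgv, pp, h2) {
  if (length(pgv) != length(pp) || length(pgv) < 3) {
    stop_stagegs("`pgv` and `pp` must be equal-length vectors of length >= 3.")
  }
  if (h2 <= 0 || h2 > 1) {
    stop_stagegs("`h2` must lie in (0, 1].")
  }
  if (sd(pgv) == 0 || sd(pp) == 0) {
    stop_stagegs("Zero variance in `pgv` or `pp`.")
  }
  pa <- cor(pgv, pp)
  slope <- unname(coef(lm(pp ~ pgv))[2])
  tibble::tibble(
    pa = pa,
    accuracy = gs_accuracy(pa, h2),
    bias = 1 - slope,
    n = length(pgv)
  )
}

#' Accuracy from predictive ability and heritability
#'
#' `accuracy = pa / sqrt(h2)`: the correlation between predicted and true
#' genetic values implied by a predictive ability measured against
#' heritability-limited pseudo-phenotypes.
#'
#' @param pa Predictive ability (correlation).
#' @param h2 Trait heritability in (0, 1].
#' @return Numeric accuracy.
#' @export
gs_accuracy <- function(pa, h2) {
  if (any(h2 <= 0 | h2 > 1)) {
    stop_stagegs("`h2` must lie in (0, 1].")
  }
  pa / sqrt(h2)
}

#' Ten-fold clone-level cross-validation of BLUP predictions
#'
#' Clones are randomly partitioned into `k` folds. For each fold, variance
#' components are re-estimated on the training records alone and the
#' mixed-model equations are solved with the validation clones' records
#' deleted; their predicted genetic values then come entirely through
#' kinship ties to the training clones. Validation targets are the
#' pseudo-phenotypes from the full-data fit (fixed across folds), and the
#' heritability in the accuracy denominator is the full-data estimate of the
#' same analysis.
#'
#' @inheritParams fit_blup
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param full_fit Optionally, a pre-computed full-data [fit_blup()] for this
#'   trait/kinship (saves one REML fit).
#' @return An object of class `gs_cv`: list with `folds` (per-fold tibble of
#'   `fold`, `pa`, `accuracy`, `bias`, `n`), `summary` (mean and sd across
#'   folds), `h2`, `trait`, `kind`, `k`, `seed`, `full_fit`.
#' @export
cross_validate <- function(records, trait, K,
                           kind = c("pedigree", "genomic"),
                           k = 10, seed = 1L, interaction = TRUE,
                           blend = NULL, full_fit = NULL, ...) {
  kind <- match.arg(kind)
  if (is.null(full_fit)) {
    full_fit <- fit_blup(records, trait, K,
      kind = kind,
      interaction = interaction, blend = blend, ...
    )
  }
  h2 <- full_fit$vc$h2
  pp <- pseudo_phenotypes(full_fit)
  rec <- full_fit$records
  folds <- assign_folds(unique(rec$clone), k = k, seed = seed)
  rec <- dplyr::left_join(rec, folds, by = "clone")

  fold_rows <- purrr::map(seq_len(k), function(f) {
    val_clones <- folds$clone[folds$fold == f]
    if (length(val_clones) < 3) {
      rlang::warn(paste0("Fold ", f, " has fewer than 3 clones; skipped."))
      return(NULL)
    }
    train <- dplyr::filter(rec, .data$fold != f)
    int_f <- if (interaction) expand_blockdiag(K, train) else NULL
    design_f <- build_design(train, rownames(K), int_f)
    fit_f <- reml_fit(design_f, train$value, K, K_L = int_f, blend = blend, ...)
    pgv_f <- fit_f$solutions$a[val_clones]
    dat <- dplyr::filter(pp, .data$clone %in% val_clones)
    m <- prediction_metrics(pgv_f[dat$clone], dat$pp, h2)
    dplyr::bind_cols(tibble::tibble(fold = f), m)
  })
  fold_tbl <- dplyr::bind_rows(fold_rows)
  if (nrow(fold_tbl) == 0) {
    stop_stagegs("All folds were skipped; cannot summarise.")
  }
  summary <- fold_tbl %>%
    tidyr::pivot_longer(c("pa", "accuracy", "bias"),
      names_to = "metric", values_to = "value"
    ) %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop"
    )
  structure(
    list(
      folds = fold_tbl, summary = summary, h2 = h2,
      trait = trait, kind = kind, k = k, seed = seed,
      full_fit = full_fit
    ),
    class = "gs_cv"
  )
}

#' @export
print.gs_cv <- function(x, ...) {
  cat(
    x$k, "-fold clone-level CV, ", x$kind, " analysis, trait ", x$trait,
    " (h2 = ", round(x$h2, 3), ")\n",
    sep = ""
  )
  s <- x$summary
  for (m in c("pa", "accuracy", "bias")) {
    row <- s[s$metric == m, ]
    cat(sprintf("  %-9s %.2f +/- %.2f\n", m, row$mean, row$sd))
  }
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `gs_cv` object.
#' @return `tidy()`: the per-fold metrics tibble with trait/kind columns.
#' @method tidy gs_cv
#' @export
tidy.gs_cv <- function(x, ...) {
  dplyr::mutate(x$folds, trait = x$trait, kind = x$kind)
}

#' @rdname cross_validate
#' @return `glance()`: one row with mean and sd of each metric across folds.
#' @method glance gs_cv
#' @export
glance.gs_cv <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    trait = x$trait, kind = x$kind, k = x$k, h2 = x$h2,
    pa_mean = s$mean[s$metric == "pa"], pa_sd = s$sd[s$metric == "pa"],
    accuracy_mean = s$mean[s$metric == "accuracy"],
    accuracy_sd = s$sd[s$metric == "accuracy"],
    bias_mean = s$mean[s$metric == "bias"],
    bias_sd = s$sd[s$metric == "bias"]
  )
}
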