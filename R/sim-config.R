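#' Specify one selection stage of a simulated breeding program
#'
#' @param stage Stage label, one of `"CET"`, `"PYT"`, `"AYT"`, `"UYT"`
#'   (clonal evaluation, preliminary, advanced and uniform yield trials).
#' @param locations Character vector of location names used at this stage.
#' @param years Vector of trial years; clones entering the stage are split
#'   into year cohorts.
#' @param reps Complete replicates for `rcbd` trials (must be >= 2); test
#'   clones in `augmented` trials are unreplicated (`reps = 1`).
#' @param design `"augmented"` (unreplicated test clones, checks in every
#'   incomplete block) or `"rcbd"` (randomized complete blocks).
#' @param clones_fraction Fraction of the previous stage's test clones that
#'   advance into this stage (first stage: fraction of all progeny).
#' @param n_blocks Number of incomplete blocks for augmented trials; ignored
#'   for `rcbd` (where blocks are the replicates).
#' @return A list of class `stage_spec`.
#' @export
stage_spec <- function(stage, locations, years, reps = 1,
                       design = c("augmented", "rcbd"),
                       clones_fraction = 1, n_blocks = 6) {
  design <- match.arg(design)
  if (!stage %in% c("CET", "PYT", "AYT", "UYT")) {
    stop_stagegs("`stage` must be one of CET, PYT, AYT, UYT.",
      class = "stagegs_config_error"
    )
  }
  if (design == "augmented" && reps != 1) {
    stop_stagegs("Augmented design implies reps = 1 for test clones.",
      class = "stagegs_config_error"
    )
  }
  if (design == "rcbd" && reps < 2) {
    stop_stagegs("RCBD requires reps >= 2.", class = "stagegs_config_error")
  }
  if (clones_fraction <= 0 || clones_fraction > 1) {
    stop_stagegs("`clones_fraction` must lie in (0, 1].",
      class = "stagegs_config_error"
    )
  }
  structure(
    list(
      stage = stage, locations = as.character(locations),
      years = as.character(years), reps = as.integer(reps),
      design = design, clones_fraction = clones_fraction,
      n_blocks = as.integer(n_blocks)
    ),
    class = "stage_spec"
  )
}

#' Default per-trait variance components for the simulator
#'
#' Trait means and (additive, genotype-by-location, residual) variances for
#' the five cassava traits, back-derived from plot-level heritabilities of
#' 0.47-0.73, interaction ratios of 0-0.12 and residual coefficients of
#' variation typical of single-row clonal evaluation trials. Units: FRY, DY
#' and FSY in t/ha, DMC and HI in percent.
#'
#' @return Tibble with columns `trait`, `mean`, `sigma2_a`, `sigma2_aL`,
#'   `sigma2_e`.
#' @export
default_trait_vc <- function() {
  tibble::tibble(
    trait = c("FRY", "DMC", "DY", "FSY", "HI"),
    mean = c(29.24, 33.49, 9.63, 12.25, 70.62),
    sigma2_a = c(123.4, 7.58, 14.4, 121.1, 116.4),
    sigma2_aL = c(17.6, 0, 2.15, 30.3, 0),
    sigma2_e = c(110.8, 2.80, 14.1, 100.9, 84.3)
  )
}

#' Default four-stage trial plan
#'
#' Mirrors a multi-year cassava program: an augmented CET at 4 locations,
#' then RCBD trials with 2-3 replicates at progressively more locations
#' (5, 7 and 10 distinct locations cumulatively) while survival prunes the
#' test clones roughly 290 -> 136 -> 72 -> 21.
#'
#' @return List of [stage_spec()] objects named by stage.
#' @export
default_stage_plan <- function() {
  list(
    CET = stage_spec("CET",
      locations = c("L01", "L02", "L03", "L04"),
      years = c(2013:2016, 2018), reps = 1, design = "augmented",
      clones_fraction = 1, n_blocks = 6
    ),
    PYT = stage_spec("PYT",
      locations = c("L02", "L05"),
      years = c(2014, 2017), reps = 2, design = "rcbd",
      clones_fraction = 136 / 290
    ),
    AYT = stage_spec("AYT",
      locations = c("L02", "L04", "L06", "L07"),
      years = c(2015, 2016, 2018), reps = 3, design = "rcbd",
      clones_fraction = 72 / 136
    ),
    UYT = stage_spec("UYT",
      locations = c("L02", "L04", "L06", "L07", "L08", "L09", "L10"),
      years = 2016:2018, reps = 3, design = "rcbd",
      clones_fraction = 21 / 72
    )
  )
}

#' Configuration for a synthetic biparental-cross breeding trial
#'
#' Defaults emulate a cassava genomic-selection panel: 290 progeny from 30
#' biparental crosses among 20 founder parents (a handful of which are
#' carried through all stages as replicated checks), a four-stage trial plan
#' over 10 locations and 6 years, GBS-scale missingness of 3.34%, and trait
#' variance components giving plot-level heritabilities between roughly 0.4
#' and 0.7.
#'
#' @param n_founders Number of founder parents (>= 2).
#' @param n_crosses Number of biparental crosses (>= 1); self-crosses are
#'   permitted via `allow_self`.
#' @param progeny_per_cross Integer scalar or vector (length `n_crosses`).
#'   The default distributes 290 progeny over 30 crosses.
#' @param n_markers Number of unlinked biallelic SNP markers.
#' @param maf_range Founder allele frequencies are drawn uniformly from this
#'   interval in (0, 0.5].
#' @param trait_vc Tibble like [default_trait_vc()]: `trait`, `mean`,
#'   `sigma2_a`, `sigma2_aL`, `sigma2_e` (trait units squared).
#' @param stage_plan List of [stage_spec()]s, e.g. [default_stage_plan()].
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param n_checks Number of founders carried as replicated checks in every
#'   trial.
#' @param env_var_ratio Variance of the year-location-block environmental
#'   effects as a multiple of each trait's residual variance.
#' @param selection `"index"` (stage survival by a noisy selection index,
#'   mimicking selection-driven unbalance) or `"random"`.
#' @param allow_self Allow self-crosses when sampling cross parents.
#' @param seed Integer seed; the same configuration reproduces the same
#'   population and records bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20,
                       n_crosses = 30,
                       progeny_per_cross = rep(c(10L, 9L), c(20, 10)),
                       n_markers = 5000,
                       maf_range = c(0.05, 0.5),
                       trait_vc = default_trait_vc(),
                       stage_plan = default_stage_plan(),
                       missing_rate = 0.0334,
                       n_checks = 5,
                       env_var_ratio = 0.25,
                       selection = c("index", "random"),
                       allow_self = TRUE,
                       seed = 1L) {
  selection <- match.arg(selection)
  if (n_founders < 2) {
    stop_stagegs("Need at least 2 founders.", class = "stagegs_config_error")
  }
  if (n_crosses < 1) {
    stop_stagegs("Need at least 1 cross.", class = "stagegs_config_error")
  }
  if (length(progeny_per_cross) == 1) {
    progeny_per_cross <- rep(as.integer(progeny_per_cross), n_crosses)
  }
  if (length(progeny_per_cross) != n_crosses || any(progeny_per_cross < 1)) {
    stop_stagegs(
      "`progeny_per_cross` must be a positive scalar or length-n_crosses vector.",
      class = "stagegs_config_error"
    )
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
    maf_range[1] > maf_range[2]) {
    stop_stagegs("`maf_range` must lie within (0, 0.5].",
      class = "stagegs_config_error"
    )
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_stagegs("`missing_rate` must lie in [0, 1).",
      class = "stagegs_config_error"
    )
  }
  trait_vc <- as_tibble(trait_vc)
  need <- c("trait", "mean", "sigma2_a", "sigma2_aL", "sigma2_e")
  if (!all(need %in% names(trait_vc))) {
    stop_stagegs(
      "`trait_vc` needs columns trait, mean, sigma2_a, sigma2_aL, sigma2_e.",
      class = "stagegs_config_error"
    )
  }
  if (any(trait_vc$sigma2_a < 0) || any(trait_vc$sigma2_aL < 0) ||
    any(trait_vc$sigma2_e < 0)) {
    stop_stagegs("Variance components must be non-negative.",
      class = "stagegs_config_error"
    )
  }
  if (length(stage_plan) == 0) {
    stop_stagegs("`stage_plan` must be non-empty.",
      class = "stagegs_config_error"
    )
  }
  stopifnot(all(purrr::map_lgl(stage_plan, inherits, "stage_spec")))
  n_checks <- min(n_checks, n_founders)
  structure(
    list(
      n_founders = as.integer(n_founders),
      n_crosses = as.integer(n_crosses),
      progeny_per_cross = as.integer(progeny_per_cross),
      n_markers = as.integer(n_markers),
      maf_range = maf_range,
      trait_vc = trait_vc,
      stage_plan = stage_plan,
      missing_rate = missing_rate,
      n_checks = as.integer(n_checks),
      env_var_ratio = env_var_ratio,
      selection = selection,
      allow_self = allow_self,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(
    "  founders: ", x$n_founders, ", crosses: ", x$n_crosses,
    ", progeny: ", sum(x$progeny_per_cross), "\n",
    sep = ""
  )
  cat(
    "  markers: ", x$n_markers, " (MAF in [",
    x$maf_range[1], ", ", x$maf_range[2], "], missing rate ",
    x$missing_rate, ")\n",
    sep = ""
  )
  cat(
    "  traits: ", paste(x$trait_vc$trait, collapse = ", "),
    "; stages: ", paste(purrr::map_chr(x$stage_plan, "stage"), collapse = " -> "),
    "\n  seed: ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
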