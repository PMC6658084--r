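# internal: Mendelian segregation at unlinked loci — each progeny draws one
# allele per parent per marker (gamete allele is 1 w.p. dosage/2)
mendelian_progeny <- function(dosage_sire, dosage_dam, n_progeny) {
  m <- length(dosage_sire)
  gam_s <- matrix(rbinom(n_progeny * m, 1L, rep(dosage_sire / 2, each = n_progeny)),
    nrow = n_progeny
  )
  gam_d <- matrix(rbinom(n_progeny * m, 1L, rep(dosage_dam / 2, each = n_progeny)),
    nrow = n_progeny
  )
  gam_s + gam_d
}

#' Simulate founders, biparental crosses and genetic truth
#'
#' Founder genotypes are drawn marker-by-marker from Hardy-Weinberg
#' proportions at an allele frequency sampled from `maf_range`; each progeny
#' receives one random allele from each parent independently per marker
#' (unlinked loci, Mendelian segregation). Marker effects are drawn i.i.d.
#' normal per trait and rescaled so that the variance of true breeding values
#' over the simulated clones equals the configured additive variance exactly,
#' making heritability-recovery experiments well defined. True
#' genotype-by-location effects are drawn per location from
#' `N(0, sigma2_aL * A)` (kinship-correlated within a location, independent
#' across locations), matching the block-diagonal interaction model.
#'
#' @param config A [sim_config()].
#' @return An object of class `gs_population`: list with `genotypes`
#'   (clones x markers dosages, founders first), `pedigree` (tibble
#'   `clone`/`sire`/`dam`), `marker_effects` (markers x traits), `true_bv`
#'   (clones x traits), `true_gxl` (tibble `clone`, `location`, `trait`,
#'   `effect`), `founders`, `progeny`, `checks` (ID vectors) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  m <- config$n_markers
  founders <- sprintf("F%02d", seq_len(nf))

  p <- runif(m, config$maf_range[1], config$maf_range[2])
  geno_f <- matrix(
    rbinom(nf * m, 2L, rep(p, each = nf)),
    nrow = nf, dimnames = list(founders, sprintf("M%05d", seq_len(m)))
  )

  # sample cross parents (unordered pairs, optionally selfs)
  pairs <- expand.grid(s = seq_len(nf), d = seq_len(nf))
  pairs <- pairs[pairs$s <= pairs$d, ]
  if (!config$allow_self) pairs <- pairs[pairs$s < pairs$d, ]
  take <- sample(nrow(pairs), config$n_crosses, replace = nrow(pairs) < config$n_crosses)
  crosses <- pairs[take, , drop = FALSE]

  prog_list <- vector("list", config$n_crosses)
  ped_list <- vector("list", config$n_crosses)
  for (k in seq_len(config$n_crosses)) {
    np <- config$progeny_per_cross[k]
    prog <- mendelian_progeny(geno_f[crosses$s[k], ], geno_f[crosses$d[k], ], np)
    rownames(prog) <- sprintf("X%02d_%02d", k, seq_len(np))
    prog_list[[k]] <- prog
    ped_list[[k]] <- tibble::tibble(
      clone = rownames(prog),
      sire = founders[crosses$s[k]],
      dam = founders[crosses$d[k]]
    )
  }
  geno_p <- do.call(rbind, prog_list)
  colnames(geno_p) <- colnames(geno_f)
  geno <- rbind(geno_f, geno_p)

  pedigree <- dplyr::bind_rows(
    tibble::tibble(clone = founders, sire = NA_character_, dam = NA_character_),
    dplyr::bind_rows(ped_list)
  )

  # marker effects scaled so var(true BV) hits sigma2_a exactly per trait
  Mc <- sweep(geno, 2L, colMeans(geno), `-`)
  traits <- config$trait_vc$trait
  effects <- matrix(rnorm(m * length(traits)),
    nrow = m,
    dimnames = list(colnames(geno), traits)
  )
  for (j in seq_along(traits)) {
    bv0 <- as.numeric(Mc %*% effects[, j])
    v0 <- var(bv0)
    s2a <- config$trait_vc$sigma2_a[j]
    scl <- if (v0 > 0 && s2a > 0) sqrt(s2a / v0) else 0
    effects[, j] <- effects[, j] * scl
  }
  true_bv <- Mc %*% effects

  # genotype x location deviations, kinship-correlated within location
  locations <- sort(unique(unlist(purrr::map(config$stage_plan, "locations"))))
  A <- pedigree_A(pedigree)
  A <- A[rownames(geno), rownames(geno)] # match genotype order
  LA <- chol(A)
  gxl <- purrr::map(seq_along(traits), function(j) {
    s2 <- config$trait_vc$sigma2_aL[j]
    purrr::map(locations, function(loc) {
      eff <- if (s2 > 0) {
        as.numeric(crossprod(LA, rnorm(nrow(A)))) * sqrt(s2)
      } else {
        rep(0, nrow(A))
      }
      tibble::tibble(
        clone = rownames(geno), location = loc,
        trait = traits[j], effect = eff
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()

  checks <- founders[seq_len(config$n_checks)]
  structure(
    list(
      genotypes = geno,
      pedigree = pedigree,
      marker_effects = effects,
      true_bv = true_bv,
      true_gxl = gxl,
      founders = founders,
      progeny = rownames(geno_p),
      checks = checks,
      config = config
    ),
    class = "gs_population"
  )
}

#' @export
print.gs_population <- function(x, ...) {
  cat(
    "Simulated population: ", length(x$founders), " founders, ",
    length(x$progeny), " progeny from ", x$config$n_crosses, " crosses, ",
    ncol(x$genotypes), " markers, traits: ",
    paste(colnames(x$true_bv), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate multi-stage, multi-location trial records
#'
#' Each phenotypic record is built as
#' `y = mu + env(year, location, block) + a(clone) + aL(clone, location) + e`,
#' with environmental effects drawn once per year-location-block combination
#' (variance `env_var_ratio * sigma2_e`), additive and interaction truth taken
#' from the population object, and i.i.d. residuals. Stage survival keeps a
#' nested subset of test clones (top clones by a noisy index by default,
#' mimicking selection-driven unbalance), while check clones are replicated
#' across all stages, locations and years. Later stages therefore contain
#' fewer clones evaluated at more locations.
#'
#' @param pop A [simulate_population()] result.
#' @param config The same [sim_config()] (defaults to `pop$config`).
#' @return Long-format tibble of records: `clone`, `stage`, `location`,
#'   `year`, `block`, `rep`, `trait`, `value`.
#' @export
simulate_trials <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "gs_population"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  traits <- config$trait_vc$trait
  mu <- setNames(config$trait_vc$mean, traits)
  s2e <- setNames(config$trait_vc$sigma2_e, traits)
  s2env <- config$env_var_ratio * s2e

  gxl_key <- paste(pop$true_gxl$clone, pop$true_gxl$location, pop$true_gxl$trait)
  gxl_val <- setNames(pop$true_gxl$effect, gxl_key)

  # noisy selection score used for stage survival
  bv_std <- scale(pop$true_bv)
  score <- rowSums(bv_std) + rnorm(nrow(bv_std), sd = sqrt(ncol(bv_std)))
  names(score) <- rownames(pop$true_bv)

  current <- pop$progeny
  out <- vector("list", length(config$stage_plan))
  for (si in seq_along(config$stage_plan)) {
    sp <- config$stage_plan[[si]]
    n_keep <- ceiling(sp$clones_fraction * length(current))
    if (n_keep < 1 || length(current) == 0) {
      stop_stagegs(paste0("Stage ", sp$stage, " has zero clones."),
        class = "stagegs_config_error"
      )
    }
    current <- if (config$selection == "index") {
      current[order(score[current], decreasing = TRUE)[seq_len(n_keep)]]
    } else {
      sort(sample(current, n_keep))
    }
    # year cohorts: split test clones round-robin over the stage's years
    cohort <- setNames(
      sp$years[(seq_along(current) - 1L) %% length(sp$years) + 1L],
      current
    )
    rows <- purrr::map(sp$years, function(yr) {
      test <- names(cohort)[cohort == yr]
      purrr::map(sp$locations, function(loc) {
        if (sp$design == "rcbd") {
          blocks <- seq_len(sp$reps)
          cl <- c(test, pop$checks)
          tibble::tibble(
            clone = rep(cl, times = length(blocks)),
            stage = sp$stage, location = loc, year = yr,
            block = sprintf("B%d", rep(blocks, each = length(cl))),
            rep = rep(blocks, each = length(cl))
          )
        } else {
          # augmented: test clones once, checks in every incomplete block
          nb <- max(1L, min(sp$n_blocks, length(test)))
          blk_test <- (seq_along(test) - 1L) %% nb + 1L
          dplyr::bind_rows(
            tibble::tibble(
              clone = test, stage = sp$stage, location = loc, year = yr,
              block = sprintf("B%d", blk_test), rep = 1L
            ),
            tibble::tibble(
              clone = rep(pop$checks, times = nb),
              stage = sp$stage, location = loc, year = yr,
              block = sprintf("B%d", rep(seq_len(nb), each = length(pop$checks))),
              rep = 1L
            )
          )
        }
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
    out[[si]] <- rows
  }
  plots <- dplyr::bind_rows(out)

  # one environmental effect per (year, location, block) combination per trait
  env_cells <- dplyr::distinct(plots, .data$year, .data$location, .data$block)
  env_eff <- purrr::map(traits, function(tr) {
    dplyr::mutate(env_cells,
      trait = tr,
      env = rnorm(dplyr::n(), sd = sqrt(s2env[tr]))
    )
  }) %>% dplyr::bind_rows()

  long <- tidyr::crossing(plots, trait = traits) %>%
    dplyr::left_join(env_eff, by = c("year", "location", "block", "trait"))
  a <- pop$true_bv[cbind(long$clone, long$trait)]
  aL <- gxl_val[paste(long$clone, long$location, long$trait)]
  aL[is.na(aL)] <- 0
  long$value <- mu[long$trait] + long$env + a + aL +
    rnorm(nrow(long), sd = sqrt(s2e[long$trait]))
  long %>%
    dplyr::select(
      "clone", "stage", "location", "year", "block", "rep",
      "trait", "value"
    ) %>%
    dplyr::mutate(year = as.character(.data$year)) %>%
    dplyr::arrange(
      factor(.data$stage, levels = c("CET", "PYT", "AYT", "UYT")),
      .data$location, .data$year, .data$block, .data$clone, .data$trait
    )
}

#' Mask genotype calls as missing
#'
#' Sets each dosage entry to `NA` independently with probability
#' `missing_rate`, emulating GBS-style missingness before imputation.
#'
#' @param geno Clones x markers dosage matrix.
#' @param missing_rate Probability in `[0, 1)` for each entry.
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @return The matrix with masked entries set to `NA`.
#' @export
mask_genotypes <- function(geno, missing_rate, seed = 1L) {
  check_dosage(geno)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_stagegs("`missing_rate` must lie in [0, 1).",
      class = "stagegs_config_error"
    )
  }
  if (missing_rate == 0) {
    return(geno)
  }
  set.seed(seed)
  mask <- matrix(runif(length(geno)) < missing_rate, nrow = nrow(geno))
  geno[mask] <- NA
  geno
}
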