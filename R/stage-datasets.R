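STAGE_ORDER <- c("CET", "PYT", "AYT", "UYT")

#' Assemble a cumulative stage dataset
#'
#' Concatenates the records of the first `n_stages` selection stages
#' (CET, then PYT, AYT, UYT — cumulative prefixes only) and computes the
#' bookkeeping used to compare analyses across stage depths: distinct
#' locations and years, record and clone counts. The clone universe is fixed
#' by the genotyped set, so the clone count does not grow with stages.
#'
#' @param records Long-format records with a `stage` column.
#' @param n_stages How many stages to include, 1 to 4.
#' @return Object of class `stage_dataset`: list with `records`,
#'   `n_stages`, `stages`, `locations`, `years`, `n_records` (distinct
#'   plots), `n_clones`.
#' @export
assemble_stage_dataset <- function(records, n_stages) {
  records <- as_tibble(records)
  if (!"stage" %in% names(records)) {
    stop_stagegs("`records` needs a `stage` column.")
  }
  if (!n_stages %in% 1:4) {
    stop_stagegs("`n_stages` must be 1, 2, 3 or 4.",
      class = "stagegs_config_error"
    )
  }
  wanted <- STAGE_ORDER[seq_len(n_stages)]
  present <- unique(records$stage)
  absent <- setdiff(wanted, present)
  if (length(absent)) {
    stop_stagegs(paste0(
      "Requested stage(s) absent from records: ",
      paste(absent, collapse = ", ")
    ))
  }
  rec <- dplyr::filter(records, .data$stage %in% wanted)
  # one plot = one (clone, stage, location, year, block, rep) combination
  plots <- dplyr::distinct(
    rec, .data$clone, .data$stage, .data$location,
    .data$year, .data$block, .data$rep
  )
  structure(
    list(
      records = rec,
      n_stages = as.integer(n_stages),
      stages = wanted,
      locations = sort(unique(as.character(rec$location))),
      years = sort(unique(as.character(rec$year))),
      n_records = nrow(plots),
      n_clones = dplyr::n_distinct(rec$clone)
    ),
    class = "stage_dataset"
  )
}

#' @export
print.stage_dataset <- function(x, ...) {
  cat(
    x$n_stages, "-stage dataset (", paste(x$stages, collapse = " + "), "): ",
    x$n_records, " records, ", x$n_clones, " clones, ",
    length(x$locations), " locations, ", length(x$years), " years\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.stage_dataset <- function(x, ...) {
  tibble::tibble(
    n_stages = x$n_stages,
    stages = paste(x$stages, collapse = "+"),
    n_locations = length(x$locations),
    n_years = length(x$years),
    n_records = x$n_records,
    n_clones = x$n_clones
  )
}

#' Derive dry yield from fresh root yield and dry matter content
#'
#' Adds DY records computed as `FRY * DMC / 100` (t/ha) for plots where both
#' parent traits are present and DY is absent, since dry yield is defined as
#' the product of fresh root yield and dry matter content.
#'
#' @param records Long-format records.
#' @return Records with DY rows appended where they could be derived; a
#'   message reports how many were added.
#' @export
add_derived_dy <- function(records) {
  records <- as_tibble(records)
  if ("DY" %in% records$trait) {
    return(records)
  }
  keys <- c("clone", "stage", "location", "year", "block", "rep")
  wide <- records %>%
    dplyr::filter(.data$trait %in% c("FRY", "DMC")) %>%
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  if (!all(c("FRY", "DMC") %in% names(wide))) {
    return(records)
  }
  dy <- wide %>%
    dplyr::filter(!is.na(.data$FRY), !is.na(.data$DMC)) %>%
    dplyr::mutate(trait = "DY", value = .data$FRY * .data$DMC / 100) %>%
    dplyr::select(dplyr::all_of(keys), "trait", "value")
  message("Derived ", nrow(dy), " DY records as FRY * DMC / 100.")
  dplyr::bind_rows(records, dy)
}

#' Run the full stage-wise pedigree/genomic BLUP pipeline
#'
#' Drives a complete analysis: simulate (or load) genotypes, pedigree and
#' phenotypes; marker QC and heterozygote imputation; A and G matrices;
#' per-trait, per-stage-count REML fits with likelihood-ratio tests of the
#' genotype and genotype-by-location effects; optional clone-level
#' cross-validation; selection index, top-fraction genetic gains and the
#' ranking coincidence between the earliest-stage genomic and deepest-stage
#' pedigree analyses.
#'
#' @param config A named list or path to a YAML file. Recognised fields:
#'   `simulate` (list of [sim_config()] arguments, or `TRUE` for defaults),
#'   or `genotypes`/`pedigree`/`phenotypes` file paths; `traits` (default:
#'   all in the data); `analyses` (subset of `"pedigree"`, `"genomic"`);
#'   `n_stages` (vector of stage depths, default `c(1, max available)`);
#'   `call_rate_min` (0.90), `maf_min` (`"auto"` = sample-size rule),
#'   `blend` (0.01 for G), `cv` (list `k`, `seed`, or `FALSE`),
#'   `index_weights`, `top_fraction` (0.10), `lrt` (`TRUE`), `seed`.
#' @param out_dir Optional directory; when given, JSON and CSV reports are
#'   written there.
#' @return A list of class `gs_report`: `qc`, `datasets`, `fits` (tibble of
#'   glance rows), `lrt`, `cv`, `bv` (all breeding values), `selection`
#'   (index, gains, overlap), `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(
    list(
      simulate = TRUE, traits = NULL, analyses = c("pedigree", "genomic"),
      n_stages = NULL, call_rate_min = 0.90, maf_min = "auto",
      blend = 0.01, cv = FALSE, index_weights = as.list(default_index_weights()),
      top_fraction = 0.10, lrt = TRUE, seed = 1L
    ),
    config
  )

  # --- data -----------------------------------------------------------------
  if (!is.null(cfg$genotypes)) {
    geno <- read_dosage(cfg$genotypes)
    ped <- read_pedigree(cfg$pedigree)
    records <- read_phenotypes(cfg$phenotypes)
  } else {
    sim_args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sc <- do.call(sim_config, sim_args)
    pop <- simulate_population(sc)
    records <- simulate_trials(pop, sc)
    geno <- mask_genotypes(pop$genotypes, sc$missing_rate, seed = sc$seed + 2L)
    ped <- pop$pedigree
  }
  records <- add_derived_dy(records)
  traits <- cfg$traits %||% sort(unique(records$trait))

  # --- QC and kinship -------------------------------------------------------
  maf_min <- if (identical(cfg$maf_min, "auto")) NULL else cfg$maf_min
  qc <- apply_qc(geno, call_rate_min = cfg$call_rate_min, maf_min = maf_min)
  geno_qc <- impute_missing(qc$genotypes)
  G <- genomic_G(geno_qc)
  A <- pedigree_A(ped)
  A <- A[rownames(G), rownames(G)] # same clone universe and order
  Kmat <- list(pedigree = A, genomic = G)

  max_stage <- max(match(unique(records$stage), STAGE_ORDER))
  depths <- cfg$n_stages %||% unique(c(1L, max_stage))
  datasets <- purrr::map(depths, ~ assemble_stage_dataset(records, .x))
  names(datasets) <- paste0("stages_", depths)

  # --- fits, LRTs, CV -------------------------------------------------------
  fits <- list()
  glances <- list()
  lrt_rows <- list()
  cv_rows <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    for (kind in cfg$analyses) {
      K <- Kmat[[kind]]
      bl <- if (kind == "genomic") cfg$blend else NULL
      for (tr in traits) {
        key <- paste(names(datasets)[d], kind, tr, sep = ".")
        fit <- fit_blup(ds$records, tr, K, kind = kind, blend = bl)
        fits[[key]] <- fit
        glances[[key]] <- dplyr::mutate(glance(fit),
          n_stages = ds$n_stages, .before = 1
        )
        if (isTRUE(cfg$lrt)) {
          fit_ng <- fit_no_genotype(ds$records, tr, K, blend = bl)
          fit_ni <- fit_blup(ds$records, tr, K,
            kind = kind,
            interaction = FALSE, blend = bl
          )
          lrt_rows[[key]] <- dplyr::bind_rows(
            dplyr::mutate(
              lrt_compare(fit$logLik, fit_ng$logLik),
              dropped = "genotype"
            ),
            dplyr::mutate(
              lrt_compare(fit$logLik, fit_ni$logLik),
              dropped = "genotype_x_location"
            )
          ) %>%
            dplyr::mutate(
              n_stages = ds$n_stages, kind = kind,
              trait = tr, .before = 1
            )
        }
        if (!isFALSE(cfg$cv)) {
          cv_opts <- if (isTRUE(cfg$cv)) list() else cfg$cv
          cv <- cross_validate(ds$records, tr, K,
            kind = kind,
            k = cv_opts$k %||% 10,
            seed = cv_opts$seed %||% cfg$seed,
            blend = bl, full_fit = fit
          )
          cv_rows[[key]] <- dplyr::mutate(glance(cv),
            n_stages = ds$n_stages, .before = 1
          )
        }
      }
    }
  }
  bv <- dplyr::bind_rows(purrr::imap(fits, function(f, key) {
    dplyr::mutate(tidy(f), n_stages = as.integer(sub("stages_(\\d+).*", "\\1", key)))
  }))

  # --- selection comparison: earliest genomic vs deepest pedigree ----------
  selection <- NULL
  weights <- unlist(cfg$index_weights)
  d_lo <- paste0("stages_", min(depths))
  d_hi <- paste0("stages_", max(depths))
  if (all(c("pedigree", "genomic") %in% cfg$analyses) &&
    all(names(weights) %in% traits)) {
    bv_g <- dplyr::filter(
      bv, .data$kind == "genomic",
      .data$n_stages == min(depths)
    )
    bv_p <- dplyr::filter(
      bv, .data$kind == "pedigree",
      .data$n_stages == max(depths)
    )
    si_g <- selection_index(bv_g, weights)
    si_p <- selection_index(bv_p, weights)
    n_top <- ceiling(cfg$top_fraction * nrow(si_g))
    overlap <- ranking_overlap(
      si_g$clone[seq_len(n_top)], si_p$clone[seq_len(n_top)],
      setNames(si_g$si, si_g$clone), setNames(si_p$si, si_p$clone)
    )
    trait_cor <- purrr::map_dbl(traits, function(tr) {
      g <- dplyr::filter(bv_g, .data$trait == tr)
      p <- dplyr::filter(bv_p, .data$trait == tr)
      cor(g$bv, p$bv[match(g$clone, p$clone)])
    })
    gains <- purrr::map(traits, function(tr) {
      g <- dplyr::filter(bv_g, .data$trait == tr)
      tfg <- top_fraction_gain(
        setNames(g$bv, g$clone),
        trait_mean = fits[[paste(d_lo, "genomic", tr, sep = ".")]]$trait_mean,
        fraction = cfg$top_fraction
      )
      tibble::tibble(trait = tr, gain_percent = tfg$gain_percent)
    }) %>% dplyr::bind_rows()
    si_sel <- top_fraction_gain(
      setNames(si_g$si, si_g$clone),
      trait_mean = 1, fraction = cfg$top_fraction
    )
    # per-trait gains of the index-selected set
    gains_si <- purrr::map(traits, function(tr) {
      g <- dplyr::filter(bv_g, .data$trait == tr)
      v <- setNames(g$bv, g$clone)
      mean_fit <- fits[[paste(d_lo, "genomic", tr, sep = ".")]]$trait_mean
      tibble::tibble(
        trait = tr,
        gain_percent = 100 * mean(v[intersect(si_sel$selected, names(v))]) / mean_fit
      )
    }) %>% dplyr::bind_rows()
    selection <- list(
      index_genomic = si_g, index_pedigree = si_p,
      overlap = overlap,
      gebv_ebv_correlation = tibble::tibble(trait = traits, correlation = trait_cor),
      gains_per_trait = gains, gains_index_selected = gains_si
    )
  }

  report <- structure(
    list(
      qc = qc$report,
      datasets = dplyr::bind_rows(purrr::map(datasets, tidy)),
      fits = dplyr::bind_rows(glances),
      lrt = if (length(lrt_rows)) dplyr::bind_rows(lrt_rows) else NULL,
      cv = if (length(cv_rows)) dplyr::bind_rows(cv_rows) else NULL,
      bv = bv,
      selection = selection,
      config = cfg
    ),
    class = "gs_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.gs_report <- function(x, ...) {
  cat("Stage-wise BLUP pipeline report\n")
  print(x$datasets)
  cat("\nVariance components and ratios:\n")
  print(x$fits)
  if (!is.null(x$selection)) {
    cat("\nTop-fraction ranking coincidence:\n")
    print(x$selection$overlap)
  }
  invisible(x)
}

# internal: write JSON + CSV report bundle
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_bits <- list(
    qc = report$qc, datasets = report$datasets, fits = report$fits,
    lrt = report$lrt, cv = report$cv,
    selection = if (!is.null(report$selection)) {
      list(
        overlap = report$selection$overlap,
        gebv_ebv_correlation = report$selection$gebv_ebv_correlation,
        gains_per_trait = report$selection$gains_per_trait,
        gains_index_selected = report$selection$gains_index_selected
      )
    },
    parameters = report$config[c(
      "analyses", "n_stages", "call_rate_min", "maf_min", "blend",
      "top_fraction", "seed"
    )]
  )
  jsonlite::write_json(json_bits, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  readr::write_csv(report$bv, file.path(out_dir, "breeding_values.csv"))
  if (!is.null(report$selection)) {
    readr::write_csv(
      report$selection$index_genomic,
      file.path(out_dir, "selection_index_genomic.csv")
    )
    readr::write_csv(
      report$selection$index_pedigree,
      file.path(out_dir, "selection_index_pedigree.csv")
    )
  }
  invisible(out_dir)
}
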