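test_that("fold assignment partitions clones with near-equal sizes, reproducibly", {
  ids <- sprintf("c%03d", 1:290)
  f <- assign_folds(ids, k = 10, seed = 42)
  expect_setequal(f$clone, ids)
  expect_equal(unname(table(f$fold)), rep(29L, 10), ignore_attr = TRUE)
  expect_identical(f, assign_folds(ids, k = 10, seed = 42))
  expect_false(identical(f, assign_folds(ids, k = 10, seed = 43)))

  g <- assign_folds(sprintf("c%02d", 1:23), k = 5, seed = 1)
  sizes <- table(g$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(assign_folds(ids[1:5], k = 6), class = "stagegs_config_error")
  expect_error(assign_folds(ids, k = 1), class = "stagegs_config_error")
})

test_that("pseudo-phenotypes add the per-clone mean residual to the PGV", {
  cfg <- small_sim(seed = 70, n_markers = 150)
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  A <- pedigree_A(pop$pedigree)[rownames(pop$genotypes), rownames(pop$genotypes)]
  fit <- fit_blup(rec, "DMC", A)
  pp <- pseudo_phenotypes(fit)

  # loop oracle over clones
  for (cl in pp$clone[1:10]) {
    res <- fit$records$.resid[fit$records$clone == cl]
    expect_equal(
      pp$pp[pp$clone == cl],
      unname(fit$solutions$a[cl]) + mean(res)
    )
  }
  # zero (or mean-zero) residuals leave PP = PGV
  fake <- fit
  fake$records$.resid <- 0
  pp0 <- pseudo_phenotypes(fake)
  expect_equal(pp0$pp, pp0$pgv)
})

test_that("prediction metrics reproduce closed forms and the accuracy bound", {
  # identity: perfect prediction
  set.seed(71)
  x <- rnorm(30)
  m <- prediction_metrics(x, x, h2 = 0.5)
  expect_equal(m$pa, 1)
  expect_equal(m$bias, 0, tolerance = 1e-12)

  # doubled pseudo-phenotypes: slope 2, bias -1 (underestimation)
  m2 <- prediction_metrics(x, 2 * x, h2 = 0.5)
  expect_equal(m2$bias, -1, tolerance = 1e-12)

  # accuracy >= predictive ability whenever h2 <= 1
  y <- x + rnorm(30)
  for (h2 in c(0.2, 0.5, 1)) {
    mm <- prediction_metrics(x, y, h2)
    expect_gte(mm$accuracy, mm$pa)
  }
  expect_error(prediction_metrics(x, y, 1.2))
  expect_error(prediction_metrics(x[1:2], y[1:2], 0.5))
  expect_error(prediction_metrics(rep(1, 10), y[1:10], 0.5))
})

test_that("cross-validation is deterministic and order-invariant given the seed", {
  cfg <- small_sim(seed = 72, n_markers = 150, two_stage = FALSE)
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  A <- pedigree_A(pop$pedigree)[rownames(pop$genotypes), rownames(pop$genotypes)]
  cv1 <- cross_validate(rec, "FRY", A, kind = "pedigree", k = 5, seed = 9)
  cv2 <- cross_validate(rec, "FRY", A, kind = "pedigree", k = 5, seed = 9)
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(cv1$summary, cv2$summary)

  # permuting record order changes nothing
  set.seed(1)
  rec_perm <- rec[sample(nrow(rec)), ]
  cv3 <- cross_validate(rec_perm, "FRY", A, kind = "pedigree", k = 5, seed = 9)
  expect_equal(cv1$summary, cv3$summary, tolerance = 1e-6)
})

test_that("genomic prediction accuracy improves with marker density", {
  # same truth, different assay density: one simulated population per
  # replicate, G built either from a random 500-marker subset or from the
  # full 5000-marker panel; accuracy measured against the true breeding
  # values of held-out clones (the quantity CV accuracy estimates)
  accs <- matrix(NA_real_, 10, 2)
  for (r in 1:10) {
    cfg <- sim_config(
      n_founders = 8, n_crosses = 8, progeny_per_cross = 12,
      n_markers = 5000, n_checks = 0,
      trait_vc = tibble::tibble(
        trait = "T", mean = 10,
        sigma2_a = 1, sigma2_aL = 0.2, sigma2_e = 0.8
      ),
      stage_plan = list(CET = stage_spec("CET",
        locations = c("L1", "L2"),
        years = "Y1", reps = 2, design = "rcbd", clones_fraction = 1
      )),
      seed = 500 + r
    )
    pop <- simulate_population(cfg)
    rec <- simulate_trials(pop)
    folds <- assign_folds(unique(rec$clone), k = 5, seed = r)
    held_out <- folds$clone[folds$fold == 1]
    train <- dplyr::filter(rec, !.data$clone %in% held_out)
    set.seed(600 + r)
    panel <- sample(ncol(pop$genotypes), 500)
    for (j in 1:2) {
      geno <- if (j == 1) pop$genotypes[, panel] else pop$genotypes
      fit <- fit_blup(train, "T", genomic_G(geno), kind = "genomic")
      accs[r, j] <- cor(fit$solutions$a[held_out], pop$true_bv[held_out, "T"])
    }
  }
  expect_gt(mean(accs[, 2]), mean(accs[, 1]))
})
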