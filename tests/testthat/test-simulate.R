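test_that("crossing an all-reference with an all-alternate parent forces heterozygotes", {
  set.seed(1)
  prog <- stagegs:::mendelian_progeny(rep(0, 50), rep(2, 50), 20)
  expect_true(all(prog == 1))
})

test_that("selfing a fully heterozygous parent segregates 1:2:1", {
  set.seed(2024)
  prog <- stagegs:::mendelian_progeny(1, 1, 400)
  counts <- tabulate(prog[, 1] + 1L, nbins = 3)
  p <- exact_multinom_p(counts, c(0.25, 0.5, 0.25))
  expect_gt(p, 0.001)
})

test_that("progeny mean dosage matches the mid-parent mean", {
  set.seed(3)
  gs <- sample(0:2, 40, replace = TRUE)
  gd <- sample(0:2, 40, replace = TRUE)
  n <- 1000
  prog <- stagegs:::mendelian_progeny(gs, gd, n)
  mid <- (gs + gd) / 2
  # dosage is a sum of two Bernoulli gametes; 3 binomial SEs per marker
  se <- sqrt(gs / 2 * (1 - gs / 2) + gd / 2 * (1 - gd / 2)) / sqrt(n)
  dev <- abs(colMeans(prog) - mid)
  expect_true(all(dev <= pmax(3 * se, 1e-12)))
})

test_that("the same seed reproduces population and records bit for bit", {
  cfg <- small_sim(seed = 11, n_markers = 120)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1, pop2)
  expect_identical(simulate_trials(pop1), simulate_trials(pop2))
  m1 <- mask_genotypes(pop1$genotypes, 0.1, seed = 5)
  m2 <- mask_genotypes(pop1$genotypes, 0.1, seed = 5)
  expect_identical(m1, m2)
})

test_that("true breeding values hit the configured additive variance exactly", {
  cfg <- small_sim(seed = 4, n_markers = 500)
  pop <- simulate_population(cfg)
  v <- apply(pop$true_bv, 2, var)
  expect_equal(unname(v), cfg$trait_vc$sigma2_a, tolerance = 1e-10)
  # and the stored effects reproduce the breeding values (centered genotypes)
  Mc <- sweep(pop$genotypes, 2, colMeans(pop$genotypes))
  expect_equal(unname(Mc %*% pop$marker_effects), unname(pop$true_bv),
    tolerance = 1e-10
  )
})

test_that("all variance components zero gives records equal to the trait mean", {
  vc0 <- tibble::tibble(
    trait = "T", mean = 7,
    sigma2_a = 0, sigma2_aL = 0, sigma2_e = 0
  )
  cfg <- small_sim(seed = 5, n_markers = 60, trait_vc = vc0, env_var_ratio = 0)
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  expect_true(all(rec$value == 7))
})

test_that("within-environment record variance follows the law of total variance", {
  vc <- tibble::tibble(
    trait = "T", mean = 0,
    sigma2_a = 1, sigma2_aL = 0.5, sigma2_e = 1
  )
  cfg <- sim_config(
    n_founders = 20, n_crosses = 50, progeny_per_cross = 10,
    n_markers = 200, n_checks = 0, trait_vc = vc, env_var_ratio = 0,
    stage_plan = list(CET = stage_spec("CET",
      locations = paste0("L", 1:4),
      years = "Y1", reps = 3, design = "rcbd", clones_fraction = 1
    )),
    seed = 21
  )
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  cells <- rec %>%
    dplyr::group_by(.data$location, .data$year, .data$block) %>%
    dplyr::summarise(v = var(.data$value), n = dplyr::n(), .groups = "drop")
  expect_gte(sum(cells$n), 5000)
  pooled <- sum(cells$v * (cells$n - 1)) / sum(cells$n - 1)
  expect_equal(pooled, 2.5, tolerance = 0.10)
})

test_that("stage survival produces nested clone subsets with Table-2-style unbalance", {
  cfg <- small_sim(seed = 6, n_markers = 80)
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  by_stage <- split(rec, rec$stage)
  cet_clones <- setdiff(unique(by_stage$CET$clone), pop$checks)
  pyt_clones <- setdiff(unique(by_stage$PYT$clone), pop$checks)
  expect_true(all(pyt_clones %in% cet_clones))
  expect_lt(length(pyt_clones), length(cet_clones))
  # checks are replicated across every stage
  for (s in names(by_stage)) {
    expect_true(all(pop$checks %in% by_stage[[s]]$clone))
  }
})

test_that("masking is Bernoulli with the requested rate and rate 0 is identity", {
  cfg <- small_sim(seed = 7, n_markers = 300)
  pop <- simulate_population(cfg)
  expect_identical(mask_genotypes(pop$genotypes, 0, seed = 1), pop$genotypes)
  big <- matrix(1, 290, 10000)
  masked <- mask_genotypes(big, 0.0334, seed = 9)
  frac <- mean(is.na(masked))
  expect_gte(frac, 0.030)
  expect_lte(frac, 0.037)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_founders = 0), class = "stagegs_config_error")
  expect_error(sim_config(n_crosses = 0), class = "stagegs_config_error")
  expect_error(sim_config(maf_range = c(0, 0.6)), class = "stagegs_config_error")
  expect_error(
    stage_spec("CET", "L1", "Y1", reps = 2, design = "augmented"),
    class = "stagegs_config_error"
  )
  expect_error(
    stage_spec("PYT", "L1", "Y1", reps = 1, design = "rcbd"),
    class = "stagegs_config_error"
  )
})
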