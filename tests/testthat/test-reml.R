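test_that("REML equals ANOVA estimators on a balanced one-way layout", {
  set.seed(50)
  n_clones <- 20
  reps <- 5
  ids <- sprintf("c%02d", seq_len(n_clones))
  a <- rnorm(n_clones, 0, sqrt(3))
  rec <- tidyr::crossing(clone = ids, rep = seq_len(reps)) %>%
    dplyr::mutate(
      location = "L1", year = "Y1", block = "B1",
      value = 10 + a[match(clone, ids)] + rnorm(dplyr::n(), 0, 1)
    )
  K <- diag(n_clones)
  dimnames(K) <- list(ids, ids)
  d <- build_design(rec, ids)
  fit <- reml_fit(d, rec$value, K,
    K_L = NULL,
    tol_logl = 1e-10, tol_par = 1e-8
  )

  aov_tab <- summary(stats::aov(value ~ clone, data = rec))[[1]]
  msb <- aov_tab["clone", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]
  expect_equal(fit$vc$sigma2_e, mse, tolerance = 1e-4)
  expect_equal(fit$vc$sigma2_a, (msb - mse) / reps, tolerance = 1e-4)
})

test_that("the restricted log-likelihood matches the direct V-form computation", {
  fx <- make_fixture(301)
  fit <- reml_fit(fx$design, fx$y, fx$K, K_L = fx$int, blend = 0)
  or <- vform_oracle(
    fx$design$X, as.matrix(fx$design$Z1), as.matrix(fx$design$Z2),
    fx$y, fx$K, fx$KL,
    fit$vc$sigma2_a, fit$vc$sigma2_aL, fit$vc$sigma2_e
  )
  expect_equal(fit$logLik, or$logL, tolerance = 1e-6)
  # and the solutions at the optimum match the oracle at those components
  expect_equal(unname(fit$solutions$a), or$a, tolerance = 1e-6)
})

test_that("the restricted likelihood never decreases along accepted iterations", {
  for (seed in c(302, 303)) {
    fx <- make_fixture(seed)
    fit <- reml_fit(fx$design, fx$y, fx$K, K_L = fx$int, blend = 0)
    logl <- fit$trajectory[, ncol(fit$trajectory)]
    expect_true(all(diff(logl) >= -1e-8))
  }
})

test_that("a constant response drives all components to the lower bound with finite logL", {
  ids <- sprintf("c%02d", 1:10)
  rec <- tibble::tibble(
    clone = rep(ids, 2), location = "L1", year = "Y1", block = "B1"
  )
  K <- diag(10)
  dimnames(K) <- list(ids, ids)
  d <- build_design(rec, ids)
  fit <- reml_fit(d, rep(5, 20), K, K_L = NULL)
  expect_true(is.finite(fit$logLik))
  expect_lt(fit$vc$sigma2_a, 1e-10)
  expect_lt(fit$vc$sigma2_e, 1e-10)
})

test_that("pedigree and genomic fits of the same data give correlated breeding values", {
  cfg <- small_sim(seed = 55, n_markers = 5000)
  pop <- simulate_population(cfg)
  rec <- simulate_trials(pop)
  A <- pedigree_A(pop$pedigree)[rownames(pop$genotypes), rownames(pop$genotypes)]
  G <- genomic_G(pop$genotypes)
  fp <- fit_blup(rec, "FRY", A, kind = "pedigree")
  fg <- fit_blup(rec, "FRY", G, kind = "genomic")
  r <- cor(fp$solutions$a, fg$solutions$a[names(fp$solutions$a)])
  expect_gt(r, 0.8)
})

test_that("non-convergence raises a classed error carrying the trajectory", {
  fx <- make_fixture(304)
  err <- tryCatch(
    reml_fit(fx$design, fx$y, fx$K, K_L = fx$int, blend = 0, max_iter = 2),
    error = function(e) e
  )
  expect_s3_class(err, "stagegs_convergence_error")
  expect_true(is.matrix(err$trajectory))
})

test_that("likelihood-ratio machinery follows the chi-square reference", {
  expect_equal(lrt_compare(-100, -110)$statistic, 20)
  eq <- lrt_compare(-50, -50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(lrt_compare(-50, -50 - 3.841 / 2)$p_value, 0.05, tolerance = 0.0005)
  expect_warning(out <- lrt_compare(-110, -100), regexp = "clamped")
  expect_equal(out$statistic, 0)
  # boundary-corrected mixture halves the tail probability
  expect_equal(
    lrt_compare(-50, -51, boundary = TRUE)$p_value,
    0.5 * pchisq(2, 1, lower.tail = FALSE)
  )
})

test_that("variance ratios are simple shares of the total", {
  r <- variance_ratios(list(sigma2_a = 1, sigma2_aL = 1, sigma2_e = 2))
  expect_equal(unname(r), c(0.25, 0.25))
  expect_equal(
    unname(variance_ratios(list(sigma2_a = 0, sigma2_aL = 3, sigma2_e = 1))[1]),
    0
  )
  set.seed(60)
  for (i in 1:5) {
    v <- runif(3, 0.1, 5)
    r <- variance_ratios(list(sigma2_a = v[1], sigma2_aL = v[2], sigma2_e = v[3]))
    expect_equal(unname(r[1]), v[1] / sum(v))
    expect_equal(unname(r[2]), v[2] / sum(v))
    expect_lte(sum(r), 1)
  }
  expect_error(variance_ratios(list(sigma2_a = 0, sigma2_aL = 0, sigma2_e = 0)))
})
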