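test_that("pedigree A reproduces textbook closed forms", {
  # founders only -> identity
  ped0 <- tibble::tibble(clone = c("a", "b", "c"), sire = NA, dam = NA)
  expect_equal(unname(pedigree_A(ped0)), diag(3))

  # two unrelated parents, two full-sib offspring
  ped1 <- tibble::tibble(
    clone = c("P1", "P2", "O1", "O2"),
    sire = c(NA, NA, "P1", "P1"),
    dam = c(NA, NA, "P2", "P2")
  )
  A <- pedigree_A(ped1)
  expect_equal(unname(diag(A)), rep(1, 4))
  expect_equal(A["O1", "O2"], 0.5)
  expect_equal(A["P1", "O1"], 0.5)
  expect_equal(A["P2", "O2"], 0.5)
  expect_equal(A["P1", "P2"], 0)

  # self-cross of a non-inbred parent: offspring F = 0.5, diagonal 1.5
  ped2 <- tibble::tibble(
    clone = c("P", "S"),
    sire = c(NA, "P"), dam = c(NA, "P")
  )
  A2 <- pedigree_A(ped2)
  expect_equal(A2["S", "S"], 1.5)
  expect_equal(A2["P", "S"], 1)
})

test_that("pedigree A handles unordered input, implicit founders, and rejects cycles", {
  ped <- tibble::tibble(
    clone = c("O1", "P1"), # offspring listed before its sire
    sire = c("P1", NA),
    dam = c("P2", NA) # P2 never listed: implicit founder
  )
  A <- pedigree_A(ped)
  expect_setequal(rownames(A), c("P1", "P2", "O1"))
  expect_equal(A["P1", "O1"], 0.5)

  cyc <- tibble::tibble(
    clone = c("a", "b"),
    sire = c("b", "a"), dam = c(NA, NA)
  )
  expect_error(pedigree_A(cyc), class = "stagegs_pedigree_error")
})

test_that("pedigree A agrees with gene dropping on a 20-member pedigree", {
  set.seed(33)
  ped <- tibble::tibble(
    clone = paste0("I", 1:20),
    sire = NA_character_, dam = NA_character_
  )
  for (i in 7:20) {
    ped$sire[i] <- paste0("I", sample(i - 1, 1))
    ped$dam[i] <- paste0("I", sample(i - 1, 1)) # may equal sire: a self
  }
  A <- pedigree_A(ped)
  gd <- gene_drop_A(ped[match(rownames(A), ped$clone), ], n_drops = 50000, seed = 77)
  z <- abs(A - gd$A) / pmax(gd$se, 1e-12)
  z[gd$se == 0] <- 0
  zs <- z[upper.tri(z, diag = TRUE)]
  expect_lte(mean(zs > 3), 0.01) # chance exceedances among 210 comparisons
  expect_lt(max(zs), 5)
})

test_that("pedigree A is positive definite for valid pedigrees", {
  cfg <- small_sim(seed = 8, n_markers = 50)
  pop <- simulate_population(cfg)
  A <- pedigree_A(pop$pedigree)
  expect_silent(chol(A))
})

test_that("VanRaden G matches hand computation and annihilates the ones vector", {
  geno <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "m1"))
  G <- genomic_G(geno)
  expect_equal(unname(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))

  set.seed(20)
  g2 <- matrix(rbinom(5 * 8, 2, 0.4), 5, 8,
    dimnames = list(paste0("c", 1:5), paste0("m", 1:8))
  )
  G2 <- genomic_G(g2)
  expect_lt(abs(sum(G2)), 1e-8)

  # elementwise double-loop oracle
  p <- colMeans(g2) / 2
  denom <- sum(2 * p * (1 - p))
  O <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      for (k in 1:8) {
        O[i, j] <- O[i, j] + (g2[i, k] - 2 * p[k]) * (g2[j, k] - 2 * p[k])
      }
    }
  }
  expect_equal(unname(G2), O / denom, tolerance = 1e-12)

  expect_error(genomic_G(matrix(NA_real_, 2, 2)), regexp = "missing|Dosages")
  expect_error(
    genomic_G(matrix(2, 3, 4, dimnames = list(paste0("c", 1:3), paste0("m", 1:4)))),
    class = "stagegs_qc_error"
  )
})

test_that("realized genomic relationships track pedigree expectations", {
  # a founder-dominated panel keeps the allele-frequency reference close to
  # the base population, where E[G] = A holds
  cfg <- sim_config(
    n_founders = 100, n_crosses = 10, progeny_per_cross = 4,
    n_markers = 5000, n_checks = 0, allow_self = FALSE, seed = 41
  )
  pop <- simulate_population(cfg)
  G <- genomic_G(pop$genotypes)
  # unselected founders drawn at Hardy-Weinberg: mean diagonal near 1
  expect_equal(mean(diag(G)[pop$founders]), 1, tolerance = 0.05)
  # full sibs average near 0.5
  fam <- split(
    pop$pedigree$clone[!is.na(pop$pedigree$sire)],
    paste(pop$pedigree$sire, pop$pedigree$dam)[!is.na(pop$pedigree$sire)]
  )
  sib_vals <- unlist(lapply(fam, function(cl) {
    M <- G[cl, cl]
    M[upper.tri(M)]
  }))
  expect_lt(abs(mean(sib_vals) - 0.5), 0.05)
})

test_that("block-diagonal expansion indexes per-location clone sets correctly", {
  K <- diag(3)
  dimnames(K) <- list(c("c1", "c2", "c3"), c("c1", "c2", "c3"))
  rec <- tibble::tibble(
    clone = c("c1", "c2", "c1", "c3"),
    location = c("A", "A", "B", "B")
  )
  int <- expand_blockdiag(K, rec)
  expect_equal(int$dim, 4)
  expect_equal(unname(sapply(int$clone_sets, length)), c(2, 2))
  expect_equal(int$locations, c("A", "B"))

  # single location covering all clones: the block is K itself
  rec1 <- tibble::tibble(clone = c("c1", "c2", "c3"), location = "A")
  int1 <- expand_blockdiag(K, rec1)
  expect_equal(int1$blocks[[1]], K)
  expect_equal(as.matrix(int1)[1:3, 1:3], unname(K), ignore_attr = TRUE)

  # simulated multi-stage records: dimension equals an independent count
  cfg <- small_sim(seed = 9, n_markers = 60)
  pop <- simulate_population(cfg)
  recs <- simulate_trials(pop)
  A <- pedigree_A(pop$pedigree)
  int2 <- expand_blockdiag(A, recs)
  n_pairs <- nrow(unique(recs[, c("location", "clone")]))
  expect_equal(int2$dim, n_pairs)

  expect_error(expand_blockdiag(K, tibble::tibble(clone = "cX", location = "A")))
})

test_that("stabilized inverse is exact when unblended and repairs rank deficiency", {
  expect_equal(stabilized_inverse(diag(4), blend = 0), diag(4))

  set.seed(21)
  K <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6)
  Ki <- stabilized_inverse(K, blend = 0)
  expect_equal(K %*% Ki, diag(6), tolerance = 1e-8)

  # G from 3 clones and 1 marker is rank 1: default blend makes it invertible
  g <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  G <- genomic_G(g)
  expect_error(stabilized_inverse(G, blend = 0), class = "stagegs_singular_error")
  Gi <- stabilized_inverse(G) # default blend 0.01
  Gb <- 0.99 * G + 0.01 * diag(3)
  expect_equal(unname(Gb %*% Gi), diag(3), tolerance = 1e-8)
})
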