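# Independent oracles used across the suite. These deliberately take the
# slow, direct route (dense V matrix, elementwise loops, enumeration,
# gene dropping) so they share no code path with the package internals.

# Direct GLS/BLUP through the phenotypic covariance matrix:
#   V = Z1 K Z1' s2a + Z2 KL Z2' s2aL + I s2e
#   b = (X'V^-1X)^-1 X'V^-1 y;  a = s2a K Z1' V^-1 (y - Xb)
vform_oracle <- function(X, Z1, Z2, y, K, KL, s2a, s2aL, s2e) {
  n <- length(y)
  V <- s2a * Z1 %*% K %*% t(Z1) + s2e * diag(n)
  if (!is.null(Z2)) V <- V + s2aL * Z2 %*% KL %*% t(Z2)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% b
  a <- s2a * K %*% crossprod(Z1, Vi %*% r)
  aL <- if (!is.null(Z2)) s2aL * KL %*% crossprod(Z2, Vi %*% r) else NULL
  p <- ncol(X)
  quad <- as.numeric(crossprod(r, Vi %*% r))
  logL <- -0.5 * (determinant(V)$modulus + determinant(XtVi %*% X)$modulus +
    quad + (n - p) * log(2 * pi))
  list(
    b = as.numeric(b), a = as.numeric(a), aL = as.numeric(aL),
    logL = as.numeric(logL)
  )
}

# A small seeded mixed-model fixture: family-structured pedigree K,
# random multi-environment records, known variance components.
make_fixture <- function(seed, n_prog = 8, n_loc = 2,
                         s2a = 2, s2aL = 0.7, s2e = 1) {
  set.seed(seed)
  ped <- dplyr::bind_rows(
    tibble::tibble(clone = c("P1", "P2", "P3"), sire = NA, dam = NA),
    tibble::tibble(
      clone = sprintf("O%02d", seq_len(n_prog)),
      sire = sample(c("P1", "P2"), n_prog, replace = TRUE),
      dam = sample(c("P2", "P3"), n_prog, replace = TRUE)
    )
  )
  K <- pedigree_A(ped)
  clones <- rownames(K)
  locs <- paste0("L", seq_len(n_loc))
  rec <- tidyr::crossing(
    clone = clones, location = locs,
    year = c("Y1", "Y2"), block = "B1"
  )
  rec <- rec[sample(nrow(rec), ceiling(0.7 * nrow(rec))), ]
  rec$value <- rnorm(nrow(rec), mean = 10, sd = 2)
  rec$stage <- "CET"
  rec$rep <- 1L
  rec$trait <- "T"
  int <- expand_blockdiag(K, rec)
  design <- build_design(rec, clones, int)
  list(
    records = rec, K = K, KL = as.matrix(int), int = int,
    design = design, y = rec$value,
    vc = list(sigma2_a = s2a, sigma2_aL = s2aL, sigma2_e = s2e)
  )
}

# Gene-dropping estimate of the additive relationship matrix: founders get
# unique alleles, each descendant inherits one random allele per parent,
# A[i,j] is estimated from identity-by-descent counts over many drops.
gene_drop_A <- function(ped, n_drops = 50000, seed = 1) {
  set.seed(seed)
  ids <- ped$clone
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      al1[, i] <- next_allele
      al2[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      pick1 <- rbinom(n_drops, 1L, 0.5) == 1L
      al1[, i] <- ifelse(pick1, al1[, si[i]], al2[, si[i]])
      pick2 <- rbinom(n_drops, 1L, 0.5) == 1L
      al2[, i] <- ifelse(pick2, al1[, di[i]], al2[, di[i]])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ids, ids))
  A_se <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        stat <- 1 + (al1[, i] == al2[, i])
      } else {
        stat <- 0.5 * ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
          (al2[, i] == al1[, j]) + (al2[, i] == al2[, j]))
      }
      A_hat[i, j] <- A_hat[j, i] <- mean(stat)
      A_se[i, j] <- A_se[j, i] <- stats::sd(stat) / sqrt(n_drops)
    }
  }
  list(A = A_hat, se = A_se)
}

# Exact multinomial goodness-of-fit p-value by enumeration over all
# outcomes of n trials in 3 categories.
exact_multinom_p <- function(obs, prob) {
  n <- sum(obs)
  p_obs <- stats::dmultinom(obs, prob = prob)
  total <- 0
  for (a in 0:n) {
    for (b in 0:(n - a)) {
      p <- stats::dmultinom(c(a, b, n - a - b), prob = prob)
      if (p <= p_obs + 1e-12) total <- total + p
    }
  }
  total
}

# A compact simulation configuration reused by several tests.
small_sim <- function(seed = 1, n_markers = 400, two_stage = TRUE, ...) {
  plan <- list(
    CET = stage_spec("CET",
      locations = c("L1", "L2"), years = c("2013", "2014"),
      reps = 1, design = "augmented", clones_fraction = 1, n_blocks = 2
    )
  )
  if (two_stage) {
    plan$PYT <- stage_spec("PYT",
      locations = c("L2", "L3"), years = "2015",
      reps = 2, design = "rcbd", clones_fraction = 0.5
    )
  }
  sim_config(
    n_founders = 8, n_crosses = 6, progeny_per_cross = 5,
    n_markers = n_markers, n_checks = 2, stage_plan = plan, seed = seed, ...
  )
}
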