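# Mixed-model equations and AI-REML for the two-random-effect clonal model
#   y = X b + Z1 a + Z2 aL + e,
#   a ~ N(0, sigma2_a K), aL ~ N(0, sigma2_aL K_L block-diagonal),
#   e ~ N(0, sigma2_e I).
# The coefficient matrix is Henderson's lambda-augmented system
#   [X'X  X'Z1            X'Z2          ]
#   [Z1'X Z1'Z1 + K^-1 l1 Z1'Z2         ]   l1 = sigma2_e / sigma2_a
#   [Z2'X Z2'Z1           Z2'Z2 + KL^-1 l2]  l2 = sigma2_e / sigma2_aL

# internal: one-time pre-computations shared by solve_mme and reml_fit
mme_prep <- function(design, y, Kinv, KLinv_blocks = NULL) {
  stopifnot(inherits(design, "design_matrices"))
  n <- length(y)
  if (nrow(design$X) != n) {
    stop_stagegs("Length of `y` does not match the design.")
  }
  Xs <- Matrix::Matrix(design$X, sparse = TRUE)
  W <- if (is.null(design$Z2)) {
    cbind(Xs, design$Z1)
  } else {
    cbind(Xs, design$Z1, design$Z2)
  }
  p <- ncol(design$X)
  q1 <- ncol(design$Z1)
  q2 <- if (is.null(design$Z2)) 0L else ncol(design$Z2)
  block_ranges <- NULL
  if (q2 > 0) {
    sizes <- purrr::map_int(KLinv_blocks, nrow)
    ends <- cumsum(sizes)
    block_ranges <- purrr::map2(ends - sizes + 1L, ends, seq)
  }
  list(
    W = W, WtW = as.matrix(Matrix::crossprod(W)),
    Wty = as.numeric(Matrix::crossprod(W, y)),
    yty = sum(y^2), y = y, n = n, p = p, q1 = q1, q2 = q2,
    idx_b = seq_len(p), idx_a = p + seq_len(q1),
    idx_L = if (q2 > 0) p + q1 + seq_len(q2) else integer(0),
    Kinv = Kinv, KLinv_blocks = KLinv_blocks, block_ranges = block_ranges
  )
}

# internal: assemble the lambda-augmented coefficient matrix
mme_C <- function(prep, lam1, lam2 = NULL) {
  C <- prep$WtW
  ia <- prep$idx_a
  C[ia, ia] <- C[ia, ia] + lam1 * prep$Kinv
  if (prep$q2 > 0) {
    off <- prep$p + prep$q1
    for (b in seq_along(prep$KLinv_blocks)) {
      r <- off + prep$block_ranges[[b]]
      C[r, r] <- C[r, r] + lam2 * prep$KLinv_blocks[[b]]
    }
  }
  C
}

# internal: per-location inverse blocks and log-determinant of K_L
kl_blocks <- function(K, interaction) {
  blocks <- purrr::map(interaction$clone_sets, function(cl) {
    K[cl, cl, drop = FALSE]
  })
  inv <- purrr::map(blocks, function(B) {
    ch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(ch)) {
      stop_stagegs(
        "A per-location kinship block is singular; increase `blend`.",
        class = "stagegs_singular_error"
      )
    }
    chol2inv(ch)
  })
  ldet <- sum(purrr::map_dbl(blocks, function(B) {
    2 * sum(log(diag(chol(B))))
  }))
  list(inv = inv, ldet = ldet)
}

#' Solve Henderson's mixed-model equations at given variance components
#'
#' Solves the lambda-augmented normal equations for fixed effects and BLUPs
#' of clone and genotype-by-location effects, with `lambda1 = sigma2_e /
#' sigma2_a` on the clone block and `lambda2 = sigma2_e / sigma2_aL` on the
#' interaction block.
#'
#' @param design A [build_design()] result.
#' @param y Numeric response vector (one trait).
#' @param Kinv Inverse of the clone relationship matrix, in the order of
#'   `design$clones` (see [stabilized_inverse()]).
#' @param KLinv Either a list of per-location inverse blocks (matching the
#'   design's interaction structure) or the dense inverse of the full
#'   block-diagonal matrix; `NULL` if the design has no interaction term.
#' @param vc List or one-row data frame with `sigma2_a`, `sigma2_e` and,
#'   when an interaction term is present, `sigma2_aL` (all > 0).
#' @return A list of class `solution_set`: `b` (named fixed-effect
#'   estimates), `a` (named clone BLUPs), `aL` (tibble `location`, `clone`,
#'   `effect`, or `NULL`), `fitted`, `residuals`.
#' @export
solve_mme <- function(design, y, Kinv, KLinv = NULL, vc) {
  vc <- as.list(vc)
  if (vc$sigma2_a <= 0 || vc$sigma2_e <= 0) {
    stop_stagegs("Variance components must be > 0 to form the MME.")
  }
  has_int <- !is.null(design$Z2)
  if (has_int && (is.null(vc$sigma2_aL) || vc$sigma2_aL <= 0)) {
    stop_stagegs("`sigma2_aL` must be > 0 when the design has an interaction term.")
  }
  blocks <- NULL
  if (has_int) {
    blocks <- if (is.list(KLinv) && !is.matrix(KLinv)) {
      KLinv
    } else {
      # slice the dense inverse into per-location blocks
      sizes <- purrr::map_int(design$interaction$clone_sets, length)
      ends <- cumsum(sizes)
      purrr::map2(ends - sizes + 1L, ends, function(a, b) {
        KLinv[a:b, a:b, drop = FALSE]
      })
    }
  }
  prep <- mme_prep(design, y, Kinv, blocks)
  lam1 <- vc$sigma2_e / vc$sigma2_a
  lam2 <- if (has_int) vc$sigma2_e / vc$sigma2_aL else NULL
  C <- mme_C(prep, lam1, lam2)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop_stagegs(
      "Singular MME coefficient matrix (check the fixed-effect constraint and kinship inverses).",
      class = "stagegs_singular_error"
    )
  }
  s <- backsolve(ch, backsolve(ch, prep$Wty, transpose = TRUE))
  mme_solutions(design, y, prep, s)
}

# internal: package an MME solution vector into a solution_set
mme_solutions <- function(design, y, prep, s) {
  b <- setNames(s[prep$idx_b], colnames(design$X))
  a <- setNames(s[prep$idx_a], design$clones)
  aL <- NULL
  if (prep$q2 > 0) {
    aL <- design$interaction$index %>%
      dplyr::mutate(effect = s[prep$idx_L]) %>%
      dplyr::select("location", "clone", "effect")
  }
  fitted <- as.numeric(prep$W %*% s)
  structure(
    list(
      b = b, a = a, aL = aL,
      fitted = fitted, residuals = y - fitted
    ),
    class = "solution_set"
  )
}

#' @export
print.solution_set <- function(x, ...) {
  cat(
    "MME solutions: ", length(x$b), " fixed effect(s), ",
    length(x$a), " clone BLUP(s)",
    if (!is.null(x$aL)) {
      paste0(", ", nrow(x$aL), " genotype x location effect(s)")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' REML estimation of variance components (average information)
#'
#' Maximizes the restricted likelihood of the two-random-effect clonal model
#' over `(sigma2_a, sigma2_aL, sigma2_e)` using average-information Newton
#' steps on Henderson's mixed-model equations, falling back to EM updates
#' whenever an AI step would leave the parameter space or decrease the
#' restricted likelihood (EM steps are monotone). Components are bounded
#' below by `1e-8 * var(y)` so that the variance ratios stay finite;
#' convergence requires both `|delta logL| < tol_logl` and a maximum relative
#' parameter change below `tol_par`.
#'
#' @param design A [build_design()] result (with or without an interaction
#'   term).
#' @param y Numeric response vector.
#' @param K Clone relationship matrix over `design$clones`.
#' @param K_L Interaction structure ([expand_blockdiag()]); defaults to the
#'   one stored in the design, `NULL` for a no-interaction model.
#' @param blend Identity blend applied to `K` (and its per-location blocks)
#'   before inversion; `NULL` (default) uses 0 when `K` is well conditioned
#'   and 0.01 otherwise.
#' @param init Optional starting values `c(sigma2_a, sigma2_aL, sigma2_e)`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol_logl,tol_par Convergence tolerances.
#' @param verbose Print the iteration trajectory.
#' @return An object of class `reml_fit`: list with `vc` (one-row tibble of
#'   components plus `h2`, `c2`), `logLik`, `n_iterations`, `converged`,
#'   `solutions` (the [solve_mme()] output at the optimum), `trajectory`,
#'   `n`, `n_clones` and the effective `blend`.
#' @export
reml_fit <- function(design, y, K, K_L = design$interaction, blend = NULL,
                     init = NULL, max_iter = 200, tol_logl = 1e-6,
                     tol_par = 1e-5, verbose = FALSE) {
  stopifnot(inherits(design, "design_matrices"))
  has_int <- !is.null(design$Z2) && !is.null(K_L)
  if (!is.null(design$Z2) && is.null(K_L)) {
    stop_stagegs("Design has an interaction term but `K_L` is NULL.")
  }
  n <- length(y)
  p <- ncol(design$X)
  used_clones <- unique(design$clones[Matrix::colSums(design$Z1) > 0])
  if (length(used_clones) < 2) {
    stop_stagegs("Need records on at least 2 distinct clones.")
  }
  if (n <= p) {
    stop_stagegs("Need more records than fixed-effect levels.")
  }
  K <- K[design$clones, design$clones]

  # condition-driven identity blend: a genomic K carries the ones vector in
  # its null space, which can round to a tiny (but positive) Cholesky pivot
  if (is.null(blend)) {
    chK0 <- tryCatch(chol(K), error = function(e) NULL)
    well_conditioned <- !is.null(chK0) &&
      min(diag(chK0))^2 > 1e-8 * max(diag(chK0))^2
    blend <- if (well_conditioned) 0 else 0.01
  }
  Kb <- blend_K(K, blend)
  chK <- tryCatch(chol(Kb), error = function(e) NULL)
  if (is.null(chK)) {
    stop_stagegs("K is singular even after blending; increase `blend`.",
      class = "stagegs_singular_error"
    )
  }
  Kinv <- chol2inv(chK)
  ldetK <- 2 * sum(log(diag(chK)))
  klb <- NULL
  if (has_int) {
    klb <- kl_blocks(Kb, K_L)
  }
  prep <- mme_prep(design, y, Kinv, if (has_int) klb$inv else NULL)
  q1 <- prep$q1
  q2 <- prep$q2

  vy <- var(y)
  scale0 <- max(vy, .Machine$double.eps)
  lb <- 1e-8 * scale0
  th <- if (!is.null(init)) {
    if (has_int) init[c(1, 2, 3)] else init[c(1, 3)]
  } else if (has_int) {
    c(0.35, 0.15, 0.5) * scale0
  } else {
    c(0.4, 0.6) * scale0
  }
  th <- pmax(th, lb)
  n_par <- length(th)

  # restricted log-likelihood and all per-iteration quantities at theta
  eval_at <- function(th) {
    s2a <- th[1]
    s2aL <- if (has_int) th[2] else NA_real_
    s2e <- th[n_par]
    lam1 <- s2e / s2a
    lam2 <- if (has_int) s2e / s2aL else NULL
    C <- mme_C(prep, lam1, lam2)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) {
      return(NULL)
    }
    s <- backsolve(ch, backsolve(ch, prep$Wty, transpose = TRUE))
    Cinv <- chol2inv(ch)
    ldetC <- 2 * sum(log(diag(ch)))
    quad <- max(prep$yty - sum(s * prep$Wty), 0)
    ldetGamma <- q1 * log(s2a / s2e) + ldetK +
      if (has_int) q2 * log(s2aL / s2e) + klb$ldet else 0
    logL <- -0.5 * ((n - p) * log(s2e) + ldetGamma + ldetC +
      quad / s2e + (n - p) * log(2 * pi))

    ua <- s[prep$idx_a]
    tra <- sum(Kinv * Cinv[prep$idx_a, prep$idx_a])
    uKu_a <- as.numeric(ua %*% (Kinv %*% ua))
    trL <- uKu_L <- 0
    if (has_int) {
      uL <- s[prep$idx_L]
      off <- p + q1
      for (b in seq_along(klb$inv)) {
        r <- prep$block_ranges[[b]]
        CL <- Cinv[off + r, off + r, drop = FALSE]
        trL <- trL + sum(klb$inv[[b]] * CL)
        ub <- uL[r]
        uKu_L <- uKu_L + as.numeric(ub %*% (klb$inv[[b]] %*% ub))
      }
    }
    resid <- prep$y - as.numeric(prep$W %*% s)
    ee <- sum(resid^2)

    # scores via standard MME trace identities
    trPVa <- (q1 - lam1 * tra) / s2a
    trPVL <- if (has_int) (q2 - lam2 * trL) / s2aL else NULL
    trP <- (n - p - q1 - q2 + lam1 * tra +
      (if (has_int) lam2 * trL else 0)) / s2e
    score <- c(
      -0.5 * (trPVa - uKu_a / s2a^2),
      if (has_int) -0.5 * (trPVL - uKu_L / s2aL^2),
      -0.5 * (trP - ee / s2e^2)
    )

    # EM updates (monotone fallback)
    em <- c(
      (uKu_a + s2e * tra) / q1,
      if (has_int) (uKu_L + s2e * trL) / q2,
      quad / (n - p)
    )

    # average-information matrix via working vectors f_i = dV/dtheta_i %*% Py
    Fm <- cbind(
      as.numeric(design$Z1 %*% (ua / s2a)),
      if (has_int) as.numeric(design$Z2 %*% (s[prep$idx_L] / s2aL)),
      resid / s2e
    )
    RHS <- as.matrix(Matrix::crossprod(prep$W, Fm))
    Sf <- backsolve(ch, backsolve(ch, RHS, transpose = TRUE))
    PF <- (Fm - as.matrix(prep$W %*% Sf)) / s2e
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2

    list(
      logL = logL, s = s, score = score, em = em, AI = AI,
      resid = resid, quad = quad
    )
  }

  traj <- matrix(NA_real_, max_iter + 1, n_par + 1)
  converged <- FALSE
  it <- 0L
  q <- eval_at(th)
  if (is.null(q)) {
    stop_stagegs("MME coefficient matrix is singular at the starting values.",
      class = "stagegs_singular_error"
    )
  }
  traj[1, ] <- c(th, q$logL)
  while (it < max_iter) {
    it <- it + 1L
    if (verbose) {
      cat(sprintf(
        "iter %3d  logL %.6f  theta %s\n", it, q$logL,
        paste(signif(th, 6), collapse = " ")
      ))
    }
    # candidate updates: AI Newton step (clamped at the bound), then
    # halved AI steps, then the monotone EM update
    cands <- list()
    free <- th > lb * (1 + 1e-6) | q$score > 0 # pinned components stay put
    step <- tryCatch(
      {
        s <- rep(0, n_par)
        s[free] <- solve(q$AI[free, free, drop = FALSE], q$score[free])
        s
      },
      error = function(e) NULL
    )
    if (!is.null(step) && all(is.finite(step))) {
      for (t in c(1, 0.5, 0.25, 0.1)) {
        cands[[length(cands) + 1]] <- pmax(th + t * step, lb)
      }
    }
    cands[[length(cands) + 1]] <- pmax(q$em, lb)
    th_new <- NULL
    q_new <- NULL
    for (prop in cands) {
      qn <- eval_at(prop)
      if (!is.null(qn) && qn$logL >= q$logL - 1e-10) {
        th_new <- prop
        q_new <- qn
        break
      }
    }
    if (is.null(th_new)) {
      # no candidate improved (flat likelihood up to round-off): accept EM
      th_new <- pmax(q$em, lb)
      q_new <- eval_at(th_new)
      if (is.null(q_new)) {
        stop_stagegs("MME coefficient matrix became singular during REML.",
          class = "stagegs_singular_error"
        )
      }
    }
    rel <- max(abs(th_new - th) / pmax(abs(th), lb))
    done <- abs(q_new$logL - q$logL) < tol_logl && rel < tol_par
    th <- th_new
    q <- q_new
    traj[it + 1, ] <- c(th, q$logL)
    if (done) {
      converged <- TRUE
      break
    }
  }
  it <- it + 1L # trajectory rows used
  if (!converged) {
    stop_stagegs(
      paste0("REML did not converge in ", max_iter, " iterations."),
      class = "stagegs_convergence_error",
      trajectory = traj[seq_len(it), , drop = FALSE]
    )
  }

  s2a <- th[1]
  s2aL <- if (has_int) th[2] else 0
  s2e <- th[n_par]
  sol <- mme_solutions(design, y, prep, q$s)
  ratios <- variance_ratios(list(
    sigma2_a = s2a, sigma2_aL = s2aL,
    sigma2_e = s2e
  ))
  structure(
    list(
      vc = tibble::tibble(
        sigma2_a = s2a, sigma2_aL = s2aL, sigma2_e = s2e,
        h2 = ratios[["h2"]], c2 = ratios[["c2"]]
      ),
      logLik = q$logL,
      n_iterations = it,
      converged = converged,
      solutions = sol,
      trajectory = traj[seq_len(it), , drop = FALSE],
      n = n, n_clones = length(used_clones),
      has_interaction = has_int, blend = blend
    ),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit (", x$n, " records, ", x$n_clones, " clones)\n", sep = "")
  cat(sprintf(
    "  sigma2_a = %.4g, sigma2_aL = %.4g, sigma2_e = %.4g\n",
    x$vc$sigma2_a, x$vc$sigma2_aL, x$vc$sigma2_e
  ))
  cat(sprintf(
    "  h2 = %.3f, c2 = %.3f, logL = %.3f (%d iterations)\n",
    x$vc$h2, x$vc$c2, x$logLik, x$n_iterations
  ))
  invisible(x)
}

#' Heritability and interaction coefficient of determination
#'
#' Plot-level ratios of the additive and genotype-by-location variances to
#' the total variance `sigma2_a + sigma2_aL + sigma2_e`.
#'
#' @param vc List or one-row data frame with `sigma2_a`, `sigma2_aL`
#'   (optional, treated as 0 when absent) and `sigma2_e`.
#' @return Named numeric vector `c(h2 = ..., c2 = ...)`.
#' @export
variance_ratios <- function(vc) {
  vc <- as.list(vc)
  s2aL <- vc$sigma2_aL %||% 0
  total <- vc$sigma2_a + s2aL + vc$sigma2_e
  if (!is.finite(total) || total <= 0) {
    stop_stagegs("Total variance must be > 0.")
  }
  c(h2 = vc$sigma2_a / total, c2 = s2aL / total)
}

#' Likelihood-ratio test between nested REML fits
#'
#' `LRT = 2 * (logL_full - logL_restricted)`, referred to the chi-square
#' upper tail. The default is a plain chi-square with 1 degree of freedom;
#' `boundary = TRUE` uses the 50:50 mixture of chi-square(0) and
#' chi-square(1) appropriate when the dropped variance component sits on the
#' boundary of its parameter space.
#'
#' @param logL_full,logL_restricted Restricted log-likelihoods of the
#'   complete and reduced models, fitted on identical data.
#' @param df Degrees of freedom (default 1).
#' @param boundary Use the boundary-corrected mixture reference.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
lrt_compare <- function(logL_full, logL_restricted, df = 1, boundary = FALSE) {
  stat <- 2 * (logL_full - logL_restricted)
  if (stat < 0) {
    rlang::warn("Negative LRT statistic clamped to 0 (full model fit worse than restricted).")
    stat <- 0
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (boundary) {
    p <- if (stat == 0) 1 else 0.5 * p
  }
  tibble::tibble(statistic = stat, df = df, p_value = p)
}
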