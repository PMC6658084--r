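#' Pedigree (numerator) relationship matrix by the tabular method
#'
#' Builds the additive relationship matrix A from clone/sire/dam triples using
#' the recursive tabular method: for individual `i` with parents `s`, `d`,
#' `A[i, j] = 0.5 * (A[j, s] + A[j, d])` for earlier `j`, and
#' `A[i, i] = 1 + 0.5 * A[s, d]`. Unknown parents contribute 0, so founders
#' are unrelated and non-inbred; inbreeding (e.g. from a self-cross) is
#' propagated through the diagonal.
#'
#' Parents that appear only in the sire/dam columns are added as founders.
#' Rows may come in any order; a topological order is established internally
#' and a cycle (an individual that is its own ancestor) is an error.
#'
#' @param ped Data frame with columns `clone`, `sire`, `dam` (character;
#'   `NA` or `""` for unknown parents).
#' @return Symmetric numeric matrix with clone IDs as dimnames, individuals
#'   in topological order.
#' @export
pedigree_A <- function(ped) {
  ped <- as_pedigree(ped)
  ids <- ped$clone
  n <- length(ids)
  si <- match(ped$sire, ids) # NA = unknown
  di <- match(ped$dam, ids)

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (is.na(s)) 0 else A[j, s]
      row_d <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (row_s + row_d)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

# internal: normalize and topologically sort a pedigree data frame
as_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  need <- c("clone", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop_stagegs("Pedigree needs columns `clone`, `sire`, `dam`.")
  }
  ped <- dplyr::mutate(
    ped,
    dplyr::across(dplyr::all_of(need), ~ {
      x <- as.character(.x)
      x[!is.na(x) & trimws(x) == ""] <- NA_character_
      x
    })
  )
  if (anyDuplicated(ped$clone)) {
    stop_stagegs("Duplicated clone IDs in pedigree.")
  }
  # implicit founders: parents never listed as clones
  parents <- setdiff(
    stats::na.omit(unique(c(ped$sire, ped$dam))),
    ped$clone
  )
  if (length(parents)) {
    ped <- dplyr::bind_rows(
      tibble::tibble(clone = parents, sire = NA_character_, dam = NA_character_),
      ped
    )
  }
  # Kahn topological sort (parents before offspring)
  ids <- ped$clone
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  placed <- rep(FALSE, length(ids))
  order_idx <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | ifelse(is.na(si), TRUE, placed[pmax(si, 1L)])) &
      (is.na(di) | ifelse(is.na(di), TRUE, placed[pmax(di, 1L)]))
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop_stagegs(
      paste0(
        "Pedigree contains a cycle involving: ",
        paste(ids[!placed], collapse = ", ")
      ),
      class = "stagegs_pedigree_error"
    )
  }
  ped[order_idx, ]
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G = Mc Mc' / sum(2 p_i q_i)` where `Mc` is the dosage matrix with
#' each column centered by twice its allele frequency `2 p_i`, and `q_i = 1 -
#' p_i`. Allele frequencies are taken from the data itself, so the column
#' centering annihilates the all-ones vector (`1' G 1 = 0`) and the average
#' diagonal is near `1 +` mean inbreeding in an unselected population.
#'
#' @param geno Clones x markers dosage matrix with no missing entries (run
#'   [impute_missing()] first).
#' @return Symmetric clones x clones matrix with clone IDs as dimnames.
#' @export
genomic_G <- function(geno) {
  check_dosage(geno)
  if (anyNA(geno)) {
    stop_stagegs("Genotypes contain missing values; run impute_missing() first.")
  }
  p <- colMeans(geno) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) {
    stop_stagegs("All markers are monomorphic; G is undefined (sum 2pq = 0).",
      class = "stagegs_qc_error"
    )
  }
  Mc <- sweep(geno, 2L, 2 * p, `-`)
  G <- tcrossprod(Mc) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

#' Center a dosage matrix by twice its allele frequencies
#'
#' The `Mc` used both in the genomic relationship matrix and in SNP-effect
#' backsolving.
#'
#' @inheritParams genomic_G
#' @return Matrix of the same shape, each column centered by `2 p_i`.
#' @export
center_markers <- function(geno) {
  check_dosage(geno)
  if (anyNA(geno)) {
    stop_stagegs("Genotypes contain missing values; run impute_missing() first.")
  }
  sweep(geno, 2L, colMeans(geno), `-`)
}

#' Stabilized inverse of a relationship matrix
#'
#' Inverts `(1 - blend) * K + blend * I`. A small identity blend keeps a
#' genomic relationship matrix invertible when markers are fewer than clones
#' or families make G rank-deficient; with `blend = 0` this is the exact
#' inverse.
#'
#' @param K Symmetric relationship matrix.
#' @param blend Identity weight in `[0, 1)`; default 0.01.
#' @return The inverse of the blended matrix, dimnames preserved.
#' @export
stabilized_inverse <- function(K, blend = 0.01) {
  if (!isSymmetric(unname(K), tol = 1e-8)) {
    stop_stagegs("`K` must be symmetric.")
  }
  Kb <- blend_K(K, blend)
  ch <- tryCatch(chol(Kb), error = function(e) NULL)
  if (is.null(ch)) {
    stop_stagegs(
      paste0("Matrix still singular after blending (blend = ", blend, ")."),
      class = "stagegs_singular_error"
    )
  }
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(K)
  out
}

# internal: (1 - blend) K + blend I
blend_K <- function(K, blend) {
  if (blend < 0 || blend >= 1) {
    stop_stagegs("`blend` must lie in [0, 1).", class = "stagegs_config_error")
  }
  if (blend == 0) {
    return(K)
  }
  (1 - blend) * K + blend * diag(nrow(K))
}

#' Per-location block-diagonal expansion of a relationship matrix
#'
#' Builds the structure behind the genotype-by-location random effect: for
#' each location (lexicographic order), the sub-matrix of `K` over the clones
#' with at least one record there; the full covariance is block-diagonal over
#' the concatenated (location, clone) pairs, so interaction effects are
#' correlated through kinship within a location and independent across
#' locations. Total dimension is the sum of per-location clone counts.
#'
#' @param K Relationship matrix (pedigree A or genomic G) whose dimnames
#'   cover every clone in `records`.
#' @param records Data frame with at least `clone` and `location` columns.
#' @return An object of class `interaction_structure`: a list with `index`
#'   (tibble of `location`, `clone`, `slot`), `locations`, `clone_sets`,
#'   `blocks` (per-location sub-matrices of `K`), and `dim`.
#' @export
expand_blockdiag <- function(K, records) {
  records <- as_tibble(records)
  if (!all(c("clone", "location") %in% names(records))) {
    stop_stagegs("`records` needs `clone` and `location` columns.")
  }
  ids <- rownames(K)
  missing_ids <- setdiff(unique(records$clone), ids)
  if (length(missing_ids)) {
    stop_stagegs(
      paste0(
        "Clones absent from the relationship matrix: ",
        paste(head(missing_ids, 5), collapse = ", "),
        if (length(missing_ids) > 5) ", ..." else ""
      )
    )
  }
  locs <- sort(unique(as.character(records$location)))
  clone_sets <- list()
  for (loc in locs) {
    cl <- unique(records$clone[records$location == loc])
    cl <- ids[ids %in% cl] # master (K) order
    if (length(cl) == 0) {
      message("Location ", loc, " has no clones; skipped.")
      next
    }
    clone_sets[[loc]] <- cl
  }
  if (length(clone_sets) == 0) {
    stop_stagegs("No location has any clone with records.")
  }
  index <- dplyr::bind_rows(purrr::imap(clone_sets, function(cl, loc) {
    tibble::tibble(location = loc, clone = cl)
  }))
  index$slot <- seq_len(nrow(index))
  blocks <- purrr::map(clone_sets, function(cl) K[cl, cl, drop = FALSE])
  structure(
    list(
      index = index,
      locations = names(clone_sets),
      clone_sets = clone_sets,
      blocks = blocks,
      dim = nrow(index)
    ),
    class = "interaction_structure"
  )
}

#' @export
print.interaction_structure <- function(x, ...) {
  cat(
    "Genotype x location structure: ", length(x$locations), " location(s), ",
    "dimension ", x$dim, " (",
    paste(purrr::map_int(x$clone_sets, length), collapse = " + "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.matrix.interaction_structure <- function(x, ...) {
  out <- matrix(0, x$dim, x$dim)
  at <- 0L
  for (b in x$blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  rn <- paste(x$index$location, x$index$clone, sep = ":")
  dimnames(out) <- list(rn, rn)
  out
}
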