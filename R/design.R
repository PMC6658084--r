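#' Build fixed- and random-effect incidence matrices
#'
#' Fixed effects are the mean plus indicators for every year x location x
#' block-within-location combination present in the records (first level
#' dropped as reference, so `X` has full column rank; a single environment
#' collapses to the intercept alone). `Z1` maps records to clones; `Z2` maps
#' records to the (location, clone) slots of an [expand_blockdiag()]
#' structure.
#'
#' @param records Tibble with columns `clone`, `location`, `year`, `block`
#'   (one row per plot record of one trait).
#' @param clones Ordered character vector of all clone IDs (the clone
#'   universe of the kinship matrix; clones without records get empty `Z1`
#'   columns and are predicted through kinship alone).
#' @param interaction An `interaction_structure` from [expand_blockdiag()],
#'   or `NULL` to omit the genotype-by-location term.
#' @return List of class `design_matrices`: `X` (dense), `Z1`, `Z2` (sparse
#'   0/1 incidence), `env` (factor of environment combinations), `clones`.
#' @export
build_design <- function(records, clones, interaction = NULL) {
  records <- as_tibble(records)
  need <- c("clone", "location", "year", "block")
  if (!all(need %in% names(records))) {
    stop_stagegs("`records` needs columns clone, location, year, block.")
  }
  if (nrow(records) == 0) {
    stop_stagegs("No records for this trait.")
  }
  unknown <- setdiff(unique(records$clone), clones)
  if (length(unknown)) {
    stop_stagegs(paste0(
      "Records reference unknown clones: ",
      paste(head(unknown, 5), collapse = ", "),
      if (length(unknown) > 5) ", ..." else ""
    ))
  }
  n <- nrow(records)
  env <- factor(paste(records$year, records$location, records$block, sep = ":"))
  X <- if (nlevels(env) > 1) {
    stats::model.matrix(~env)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL

  Z1 <- Matrix::sparseMatrix(
    i = seq_len(n), j = match(records$clone, clones),
    x = 1, dims = c(n, length(clones)),
    dimnames = list(NULL, clones)
  )
  Z2 <- NULL
  if (!is.null(interaction)) {
    stopifnot(inherits(interaction, "interaction_structure"))
    key <- paste(interaction$index$location, interaction$index$clone)
    slot <- match(paste(records$location, records$clone), key)
    if (anyNA(slot)) {
      stop_stagegs(
        "Some records' (location, clone) pairs are absent from the interaction structure."
      )
    }
    Z2 <- Matrix::sparseMatrix(
      i = seq_len(n), j = slot, x = 1,
      dims = c(n, interaction$dim)
    )
  }
  structure(
    list(X = X, Z1 = Z1, Z2 = Z2, env = env, clones = clones,
         interaction = interaction),
    class = "design_matrices"
  )
}
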