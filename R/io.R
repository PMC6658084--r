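#' Read a SNP dosage matrix
#'
#' Accepts either a delimited matrix (first column = clone ID, remaining
#' columns = markers, tab or comma separated) or the PLINK `.raw` dialect
#' (header `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP;
#' the IID column becomes the clone ID). Missing calls may be `NA` or empty.
#'
#' @param path File path.
#' @return Numeric clones x markers matrix with dimnames.
#' @export
read_dosage <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "[\t, ]+")[[1]]
  is_raw <- length(hdr) >= 6 &&
    all(toupper(hdr[1:2]) == c("FID", "IID"))
  tbl <- readr::read_delim(path,
    delim = guess_delim(path),
    show_col_types = FALSE, progress = FALSE
  )
  if (is_raw) {
    ids <- as.character(tbl[[2]])
    keep <- setdiff(
      names(tbl),
      names(tbl)[toupper(names(tbl)) %in%
        c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")]
    )
    m <- as.matrix(tbl[keep])
  } else {
    ids <- as.character(tbl[[1]])
    m <- as.matrix(tbl[-1])
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  check_dosage(m)
  m
}

# internal: sniff tab vs comma vs whitespace
guess_delim <- function(path) {
  l1 <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else " "
}

#' Write a dosage matrix as a tab-delimited file
#'
#' Header row of marker IDs, first column `clone`, missing entries written
#' as `NA`.
#'
#' @param geno Clones x markers matrix.
#' @param path Output path.
#' @export
write_dosage <- function(geno, path) {
  tbl <- dplyr::bind_cols(
    tibble::tibble(clone = rownames(geno)),
    as_tibble(geno)
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a three-column pedigree file
#'
#' CSV or TSV with columns `clone`, `sire`, `dam`; blank or `NA` parents are
#' unknown.
#'
#' @param path File path.
#' @return Tibble with character columns `clone`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_delim(path,
    delim = guess_delim(path),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(ped)[1:3] <- c("clone", "sire", "dam")
  as_pedigree(ped)
}

#' Read long-format phenotype records
#'
#' CSV/TSV with columns `clone`, `stage`, `location`, `year`, `block`,
#' `rep`, `trait`, `value`.
#'
#' @param path File path.
#' @param derive_dy Derive DY as `FRY * DMC / 100` when absent (default
#'   `TRUE`).
#' @return Tibble of records.
#' @export
read_phenotypes <- function(path, derive_dy = TRUE) {
  rec <- readr::read_delim(path,
    delim = guess_delim(path),
    show_col_types = FALSE, progress = FALSE
  )
  need <- c("clone", "stage", "location", "year", "block", "rep", "trait", "value")
  if (!all(need %in% names(rec))) {
    stop_stagegs(paste0(
      "Phenotype file must have columns: ",
      paste(need, collapse = ", ")
    ))
  }
  rec <- dplyr::mutate(
    rec,
    dplyr::across(c("clone", "stage", "location", "year", "block", "trait"), as.character),
    value = as.numeric(.data$value)
  )
  if (derive_dy) rec <- add_derived_dy(rec)
  rec
}
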