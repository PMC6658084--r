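# Published bookkeeping of the four cassava selection stages: per-stage
# record counts, location sets and trial years. Used to exercise the
# cumulative dataset assembly against printed totals.
stage_bookkeeping <- function() {
  list(
    CET = list(
      n = 964,
      locations = c("CNPMF", "NovoHorizonte", "NovoRumo", "RioDeAreia1"),
      years = c("2013", "2014", "2015", "2016", "2018")
    ),
    PYT = list(
      n = 288,
      locations = c("Capela", "NovoHorizonte"),
      years = c("2014", "2017")
    ),
    AYT = list(
      n = 388,
      locations = c("NovoHorizonte", "RioDeAreia1", "SantoAmaro", "UFRB"),
      years = c("2015", "2016", "2018")
    ),
    UYT = list(
      n = 315,
      locations = c(
        "NovoHorizonte", "RioDeAreia1", "RioDeAreia2", "SantoAmaro",
        "SaoJorge", "SombraVerde", "UFRB"
      ),
      years = c("2016", "2017", "2018")
    )
  )
}

# Expand the bookkeeping into plot records: each stage gets exactly its
# record count, cycling clones over the stage's location x year grid.
stage_records_from_bookkeeping <- function(n_clones = 290) {
  bk <- stage_bookkeeping()
  clones <- sprintf("cl%03d", seq_len(n_clones))
  dplyr::bind_rows(lapply(names(bk), function(st) {
    info <- bk[[st]]
    grid <- tidyr::crossing(location = info$locations, year = info$years)
    idx <- (seq_len(info$n) - 1L) %% nrow(grid) + 1L
    tibble::tibble(
      clone = clones[(seq_len(info$n) - 1L) %% n_clones + 1L],
      stage = st,
      location = grid$location[idx],
      year = grid$year[idx],
      block = "B1",
      rep = cumsum(rep(1L, info$n)), # unique rep index = distinct plots
      trait = "FRY",
      value = 10
    )
  }))
}
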