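# Programmatic fixtures: tiny studies built in code, no files on disk.

# one complete 7-reading series as canonical long rows
series_rows <- function(id, session, variable, values) {
  stopifnot(length(values) == 7L)
  data.frame(participant_id = id, session = session, position = 1:7,
             device = device_for_position(1:7), variable = variable,
             value = values, stringsAsFactors = FALSE)
}

# a full study: one 7-vector per participant x session x variable,
# generated by `gen(id, session, variable)`
make_study_df <- function(ids, sessions = 1:2, variables = "SBP",
                          gen = function(id, s, v) rep(120, 7)) {
  rows <- list()
  for (id in ids) for (s in sessions) for (v in variables) {
    rows[[length(rows) + 1L]] <- series_rows(id, s, v, gen(id, s, v))
  }
  if (length(rows) == 0L) {
    return(data.frame(participant_id = character(0), session = integer(0),
                      position = integer(0), device = character(0),
                      variable = character(0), value = numeric(0)))
  }
  do.call(rbind, rows)
}

# random integer-reading study for oracle comparisons: per-study device
# bias and noise drawn so both passing and failing devices occur
random_small_study <- function(n = 33L, variable = "SBP") {
  bias <- sample(c(0, 2, 4, 6, 10), 1L)
  noise <- runif(1, 1, 6)
  truth <- round(rnorm(n, 125, 15))
  rows <- list()
  for (i in seq_len(n)) for (s in 1:2) {
    latent <- truth[i] + rnorm(7, 0, noise)
    v <- round(latent + ifelse(1:7 %% 2 == 0, bias, 0) + rnorm(7, 0, 1.5))
    rows[[length(rows) + 1L]] <-
      series_rows(sprintf("S%02d", i), s, variable, v)
  }
  suppressWarnings(study_dataset(do.call(rbind, rows)))
}

# shift every test-device reading by a constant
shift_test_readings <- function(dataset, delta) {
  r <- dataset$readings
  r$value[r$device == "test"] <- r$value[r$device == "test"] + delta
  suppressWarnings(study_dataset(r, profiles = dataset$profiles,
                                 metadata = dataset$metadata))
}
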