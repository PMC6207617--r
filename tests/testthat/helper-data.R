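# small simulation setups shared across tests

# fully crossed mini-design: every indicator at every wave
mini_config <- function(n_individuals = 10, n_indicators = 2,
                        waves = c(1997, 2001), seed = 1, ...) {
  inds <- setNames(rep(list(waves), n_indicators),
                   paste0("IND", seq_len(n_indicators)))
  simulation_config(n_individuals = n_individuals, indicators = inds,
                    waves = waves, seed = seed, ...)
}

# observation table for hand-built responses: one individual per group,
# replicates spread over waves
one_way_obs <- function(values_by_group) {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(individual_id = g, indicator = "s",
               wave_year = seq(1997, by = 1, length.out = length(v)),
               age = 30, gender = 0, score_std = v,
               stringsAsFactors = FALSE)
  }))
}

expect_file_identical <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
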