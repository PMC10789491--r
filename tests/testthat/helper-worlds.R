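# Shared helpers: small deterministic worlds and cached scenario runs.

mini_config <- function(seed = 1) {
  cfg <- fixture_config()
  cfg$run$seed <- seed
  cfg
}

# cache expensive scenario runs across acceptance tests within a session
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, seed, days, burn_in_days) {
  key <- paste(name, seed, days, burn_in_days, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_scenario(name, seed = seed, days = days,
                                      burn_in_days = burn_in_days)
  }
  .run_cache[[key]]
}
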