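# Scenario definitions and runner -------------------------------------------
#
# Each scenario is reproducible from (name, seed) alone: a burn-in period
# establishes homeostasis, then the intervention schedule runs, then a
# recovery window.  Outputs: counts/staining/trajectory/event tables, a
# configuration snapshot and a manifest.

SCENARIO_NAMES <- c("homeostasis", "brdu_chase", "ki67", "stem_ablation",
                    "cdk1", "fu5_high", "fu5_low")

#' Run a named scenario
#'
#' Supported scenarios:
#' \describe{
#'   \item{homeostasis}{Burn-in plus `days` of unperturbed dynamics.}
#'   \item{brdu_chase}{Single BrdU pulse after burn-in; positional
#'     BrdU-positive fractions recorded at 2 h, 24 h and 80 h after the
#'     pulse.}
#'   \item{ki67}{Homeostasis with a positional Ki-67 staining table at the
#'     end.}
#'   \item{stem_ablation}{Targeted stem-cell ablation for 4 consecutive
#'     days (complete by 24 h, persistent thereafter), then recovery; the
#'     analysis snapshot is taken 6 h after the last induction.}
#'   \item{cdk1}{CDK1 inhibition 6 h on / every 12 h for 4 days, then
#'     recovery.}
#'   \item{fu5_high, fu5_low}{5-FU 50 (respectively 20) mg/kg every 12 h
#'     for 4 days, then recovery.}
#' }
#'
#' @param name Scenario name, one of
#'   `homeostasis, brdu_chase, ki67, stem_ablation, cdk1, fu5_high,
#'   fu5_low`.
#' @param seed RNG seed (the only source of run-to-run variation).
#' @param days Observation/recovery days after burn-in (scenario-specific
#'   default).
#' @param config Base configuration (default [default_config()]).
#' @param burn_in_days Burn-in length; defaults to
#'   `config$run$burn_in_days`.
#' @param out_dir Optional directory: writes counts/events/config/manifest
#'   files.
#' @return A `crypt_run` list: `name`, `seed`, `config`, `world` (final),
#'   `counts`, `events`, `baseline` (snapshot at end of burn-in), and
#'   scenario-specific entries (`analysis`, `staining`, ...).
#' @export
run_scenario <- function(name, seed = 1, days = NULL,
                         config = default_config(),
                         burn_in_days = config$run$burn_in_days,
                         out_dir = NULL) {
  if (!name %in% SCENARIO_NAMES) {
    stop("unknown scenario '", name, "'; available: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  }
  config$run$seed <- seed
  world <- initialize_world(config)
  burn_h <- burn_in_days * 24
  world <- run_world(world, burn_h)
  baseline <- snapshot(world)
  t0 <- world$time
  extras <- list()

  if (name %in% c("homeostasis", "ki67")) {
    days <- days %||% 20
    world <- run_world(world, days * 24)
    sel <- world$stats$ap_final_div_times >= t0
    extras$divs_at_diff <- world$stats$ap_final_divisions[sel]
    if (name == "ki67") {
      extras$staining <- positional_fraction(world, ki67_positive(world))
    }
  } else if (name == "brdu_chase") {
    days <- days %||% 4
    world <- brdu_pulse(world, t0)
    world <- run_world(world, 2)
    extras$brdu_2h <- positional_fraction(
      world, brdu_detectable(world$cells$brdu, config))
    world <- run_world(world, 22)
    extras$brdu_24h <- positional_fraction(
      world, brdu_detectable(world$cells$brdu, config))
    world <- run_world(world, 56)
    extras$brdu_80h <- positional_fraction(
      world, brdu_detectable(world$cells$brdu, config))
    rest <- days * 24 - 80
    if (rest > 0) world <- run_world(world, rest)
  } else if (name == "stem_ablation") {
    days <- days %||% 6      # recovery days after the 4-day treatment
    world$schedule$ablation <- list(start = t0, days = 4, lag = 1)
    world <- run_world(world, 4 * 24 + 6)
    extras$analysis <- snapshot(world)   # 6 h after the last induction
    extras$retro_treatment <- retrograde_frequency(world, window = 4 * 24)
    world <- run_world(world, days * 24 - 6)
    # regeneration window for dedifferentiation-origin statistics: from
    # treatment start until the stem pool first regains its homeostatic
    # size (later events are ordinary homeostatic replacement)
    cnt <- counts_frame(world)
    rec <- cnt$time[cnt$time > t0 + 4 * 24 &
                      cnt$STEM >= config$signalling$n_star]
    extras$dediff_window <- c(t0, if (length(rec)) rec[1] else
      max(cnt$time))
  } else if (name == "cdk1") {
    days <- days %||% 4
    world$schedule$cdk1 <- list(start = t0, days = 4, on_h = 6,
                                cycle_h = 12,
                                strength = config$pharmacology$cdk1_strength)
    world <- run_world(world, 4 * 24 + days * 24)
  } else if (name %in% c("fu5_high", "fu5_low")) {
    days <- days %||% 5
    dose <- if (name == "fu5_high") 50 else 20
    extras$ki67_baseline <- positional_fraction(world,
                                                ki67_positive(world))
    world$schedule$doses <- data.frame(
      time = t0 + seq(0, by = 12, length.out = 8), dose = dose)
    world <- run_world(world, 90)    # 6 h after the final dose
    extras$ki67_treat_end <- positional_fraction(world,
                                                 ki67_positive(world))
    world <- run_world(world, 4 * 24 - 90 + days * 24)
  }

  run <- structure(
    list(name = name, seed = seed, config = config, world = world,
         counts = counts_frame(world), events = event_log(world),
         baseline = baseline, t_burn_in = t0, extras = extras),
    class = "crypt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

snapshot <- function(world) {
  c(list(time = world$time,
         crypt_total = sum(!world$cells$apoptotic),
         villus_total = length(world$villus$type),
         villus_enterocytes = villus_enterocyte_count(world),
         ki67 = sum(ki67_positive(world))),
    as.list(count_types(world)))
}

#' Dedifferentiation origin composition of a run
#'
#' Tabulates dedifferentiation-into-stem events in the event log by the
#' originating cell type and returns percentages.
#'
#' @param run A `crypt_run` (or an event-log data frame).
#' @param from Optional lower time bound (h).
#' @return Named numeric vector of percentages over originating types.
#' @export
dediff_origins <- function(run, from = -Inf) {
  ev <- if (is.data.frame(run)) run else run$events
  dd <- ev[ev$event == "dedifferentiation" & ev$time >= from, ]
  if (!nrow(dd)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(dd$cell_type)
  stats::setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}

#' Write run outputs to a directory
#'
#' Writes `counts.csv`, `events.csv`, staining tables if present,
#' `config.yaml`, and `manifest.yaml` (name, seed, package version) so a
#' run can be replayed exactly.
#'
#' @param run A `crypt_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(run$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  for (nm in names(run$extras)) {
    x <- run$extras[[nm]]
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  write_config(run$config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(
    list(scenario = run$name, seed = run$seed,
         package = "cryptabm",
         version = as.character(utils::packageVersion("cryptabm")),
         burn_in_h = run$t_burn_in),
    file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Replay a run from its manifest
#'
#' @param dir Directory written by [write_run()].
#' @return A new `crypt_run` produced with the recorded scenario, seed and
#'   configuration.
#' @export
replay_run <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- read_config(file.path(dir, "config.yaml"))
  run_scenario(man$scenario, seed = man$seed, config = cfg)
}
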