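# World state and simulation loop -------------------------------------------

# Cell type codes (exactly one lineage per cell; status flags ARRESTED,
# APOPTOTIC, GIANT are orthogonal logicals).
CT_STEM <- 1L
CT_PANETH <- 2L
CT_ABSORPTIVE_PROGENITOR <- 3L
CT_SECRETORY_PROGENITOR <- 4L
CT_GOBLET <- 5L
CT_ENTEROENDOCRINE <- 6L
CT_ENTEROCYTE <- 7L

CELL_TYPE_NAMES <- c("STEM", "PANETH", "ABSORPTIVE_PROGENITOR",
                     "SECRETORY_PROGENITOR", "GOBLET", "ENTEROENDOCRINE",
                     "ENTEROCYTE")

PROLIFERATIVE_TYPES <- c(CT_STEM, CT_ABSORPTIVE_PROGENITOR,
                         CT_SECRETORY_PROGENITOR)
SECRETORY_TYPES <- c(CT_PANETH, CT_SECRETORY_PROGENITOR, CT_GOBLET,
                     CT_ENTEROENDOCRINE)

#' Cell type code lookup
#'
#' @param name Character type name(s), e.g. `"STEM"`.
#' @return Integer code(s).
#' @export
cell_type_code <- function(name) {
  match(name, CELL_TYPE_NAMES)
}

radius_from_mass <- function(mass, type, config) {
  r <- 0.5 * (mass / 1.5)^(1 / 3)
  ifelse(type == CT_PANETH, r * config$mechanics$paneth_radius_factor, r)
}

empty_cells <- function() {
  list(
    id = integer(0), type = integer(0),
    arrested = logical(0), apoptotic = logical(0), giant = logical(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    mass = numeric(0), radius = numeric(0), stiffness = numeric(0),
    wnt = numeric(0), notch = numeric(0), brdu = numeric(0),
    dna = numeric(0), rna = numeric(0),
    divisions = integer(0), birth_time = numeric(0),
    last_division_time = numeric(0), differentiation_time = numeric(0),
    arrest_time = numeric(0), ki67_memory = numeric(0),
    apopt_since = numeric(0), death_cause = character(0),
    pending_type = integer(0), pending_since = numeric(0),
    type_since = numeric(0), pure_type = logical(0),
    pure_region = logical(0), cycling = logical(0)
  )
}

append_cell <- function(world, id, type, x, y, z, mass, wnt, notch,
                        brdu = 0, dna = 0, rna = 0, divisions = 0L,
                        birth_time = world$time, cycling = NA, q = 0,
                        cycle_S = NULL, phase = 1L, stagger = NULL) {
  cl <- world$cells
  if (is.na(cycling)) cycling <- type %in% PROLIFERATIVE_TYPES
  cl$id <- c(cl$id, as.integer(id))
  cl$type <- c(cl$type, as.integer(type))
  cl$arrested <- c(cl$arrested, FALSE)
  cl$apoptotic <- c(cl$apoptotic, FALSE)
  cl$giant <- c(cl$giant, FALSE)
  cl$x <- c(cl$x, x); cl$y <- c(cl$y, y); cl$z <- c(cl$z, z)
  cl$mass <- c(cl$mass, mass)
  cl$radius <- c(cl$radius, radius_from_mass(mass, type, world$config))
  cl$stiffness <- c(cl$stiffness,
                    if (type == CT_PANETH)
                      world$config$mechanics$paneth_stiffness_factor else 1)
  cl$wnt <- c(cl$wnt, wnt); cl$notch <- c(cl$notch, notch)
  cl$brdu <- c(cl$brdu, brdu)
  cl$dna <- c(cl$dna, dna); cl$rna <- c(cl$rna, rna)
  cl$divisions <- c(cl$divisions, as.integer(divisions))
  cl$birth_time <- c(cl$birth_time, birth_time)
  cl$last_division_time <- c(cl$last_division_time, NA_real_)
  cl$differentiation_time <- c(cl$differentiation_time, NA_real_)
  cl$arrest_time <- c(cl$arrest_time, NA_real_)
  cl$ki67_memory <- c(cl$ki67_memory, if (cycling) birth_time else NA_real_)
  cl$apopt_since <- c(cl$apopt_since, NA_real_)
  cl$death_cause <- c(cl$death_cause, NA_character_)
  cl$pending_type <- c(cl$pending_type, NA_integer_)
  cl$pending_since <- c(cl$pending_since, NA_real_)
  cl$type_since <- c(cl$type_since, birth_time)
  cl$pure_type <- c(cl$pure_type, TRUE)
  cl$pure_region <- c(cl$pure_region, TRUE)
  cl$cycling <- c(cl$cycling, cycling)
  world$cells <- cl
  S <- if (!is.null(cycle_S)) cycle_S else
    cycle_state_init(1, q, world$config$cycle)
  world$cycle$S <- rbind(world$cycle$S, S)
  world$cycle$phase <- c(world$cycle$phase, as.integer(phase))
  world$cycle$b_entry <- c(world$cycle$b_entry, NA_real_)
  world$cycle$cycle_start <- c(world$cycle$cycle_start, birth_time)
  world$cycle$q <- c(world$cycle$q, q)
  world$cycle$mass_target <- c(world$cycle$mass_target,
                               world$config$cycle$mass_cap)
  world$cycle$frozen <- c(world$cycle$frozen, FALSE)
  world <- log_event(world, "birth", id, type)
  world
}

remove_cells <- function(world, rows) {
  if (!length(rows)) return(world)
  keep <- setdiff(seq_along(world$cells$id), rows)
  world$cells <- lapply(world$cells, function(v) v[keep])
  world$cycle$S <- world$cycle$S[keep, , drop = FALSE]
  world$cycle$phase <- world$cycle$phase[keep]
  world$cycle$b_entry <- world$cycle$b_entry[keep]
  world$cycle$cycle_start <- world$cycle$cycle_start[keep]
  world$cycle$q <- world$cycle$q[keep]
  world$cycle$mass_target <- world$cycle$mass_target[keep]
  world$cycle$frozen <- world$cycle$frozen[keep]
  world
}

log_event <- function(world, event, cell_id, cell_type, detail = "") {
  k <- match(cell_id, world$cells$id)
  pos <- if (!is.na(k) && length(k)) {
    surface_coords(cell_xyz(world)[k, , drop = FALSE],
                   world$config$geometry)$s
  } else NA_real_
  world$events[[length(world$events) + 1L]] <-
    list(time = world$time, event = event,
         cell_id = if (is.na(cell_id)) NA_integer_ else as.integer(cell_id),
         cell_type = if (is.na(cell_type)) NA_character_ else
           CELL_TYPE_NAMES[cell_type],
         position = pos, detail = detail)
  world
}

#' Event log as a data frame
#'
#' Append-only record of births, divisions, fate changes,
#' dedifferentiations, deaths (apoptosis, mitotic death, ablation),
#' villus transfers and shedding.  Timestamps are non-decreasing.
#'
#' @param world A `WorldState`.
#' @return Data frame with columns time, event, cell_id, cell_type,
#'   position, detail.
#' @export
event_log <- function(world) {
  ev <- world$events
  if (!length(ev)) {
    return(data.frame(time = numeric(0), event = character(0),
                      cell_id = integer(0), cell_type = character(0),
                      position = numeric(0), detail = character(0)))
  }
  data.frame(
    time = vapply(ev, `[[`, numeric(1), "time"),
    event = vapply(ev, `[[`, character(1), "event"),
    cell_id = vapply(ev, `[[`, integer(1), "cell_id"),
    cell_type = vapply(ev, `[[`, character(1), "cell_type"),
    position = vapply(ev, `[[`, numeric(1), "position"),
    detail = vapply(ev, `[[`, character(1), "detail")
  )
}

mark_death <- function(world, rows, cause) {
  cl <- world$cells
  rows <- rows[!cl$apoptotic[rows]]
  if (!length(rows)) return(world)
  cl$apoptotic[rows] <- TRUE
  cl$apopt_since[rows] <- world$time
  cl$death_cause[rows] <- cause
  cl$cycling[rows] <- FALSE
  world$cells <- cl
  world
}

#' Counts of live cells by type
#'
#' Apoptotic (not yet cleared) cells are excluded.
#'
#' @param world A `WorldState`.
#' @return Named integer vector over the seven lineages.
#' @export
count_types <- function(world) {
  alive <- !world$cells$apoptotic
  stats::setNames(
    vapply(1:7, function(tc) sum(world$cells$type == tc & alive),
           integer(1)),
    CELL_TYPE_NAMES
  )
}

#' Initialize a crypt world
#'
#' Builds a near-homeostatic crypt: stem and Paneth cells intermingled on
#' the hemispherical niche (sparse Paneth among stems, the on-off pattern
#' lateral inhibition maintains), absorptive and secretory progenitors in
#' the transit-amplifying
#' region above it with graded division counts, mature cells towards the
#' mouth, and a pre-filled villus compartment.  Cell-cycle states are
#' staggered along a template trajectory so divisions start
#' desynchronized.  Deterministic given `config$run$seed`.
#'
#' @param config Simulation configuration (see [default_config()]).
#' @return A `WorldState` list with elements `cells`, `cycle`, `villus`,
#'   `pk`, `time`, `events`, `stats`, `config`.
#' @export
initialize_world <- function(config = default_config()) {
  validate_config(config)
  set.seed(config$run$seed)
  geom <- config$geometry
  R <- geom$radius; H <- geom$height

  world <- list(
    config = config, time = 0, next_id = 1L,
    cells = empty_cells(),
    cycle = list(S = matrix(numeric(0), 0, 8,
                            dimnames = list(NULL, CYCLE_SPECIES)),
                 phase = integer(0), b_entry = numeric(0),
                 cycle_start = numeric(0), q = numeric(0),
                 mass_target = numeric(0), frozen = logical(0)),
    villus = villus_init(),
    pk = pk_init(),
    events = list(),
    schedule = list(),
    obs = list(counts = list(), traj = list(), last_record = -Inf),
    stats = list(stem_intervals = numeric(0), stem_times = numeric(0),
                 ta_intervals = numeric(0), ta_times = numeric(0),
                 ap_final_divisions = integer(0),
                 ap_final_div_times = numeric(0), shed_count = 0)
  )

  # cycle-state templates for staggered initial phases: fast cells for
  # the transit-amplifying region, slow (G1-heavy) cells for the niche
  tmpl_ta <- cycle_template(config$cycle, q = 0.05)
  tmpl_niche <- cycle_template(config$cycle, q = 0.30)

  add <- function(world, type, x, y, z, wnt, notch, divisions = 0L,
                  niche_cell = FALSE) {
    id <- world$next_id
    world$next_id <- world$next_id + 1L
    cycling <- type %in% PROLIFERATIVE_TYPES
    if (cycling) {
      tmpl <- if (niche_cell) tmpl_niche else tmpl_ta
      q0 <- if (niche_cell) 0.30 else 0.05
      u <- stats::runif(1)
      j <- 1L + floor(u * (nrow(tmpl$S) - 1L))
      world <- append_cell(world, id, type, x, y, z,
                           mass = tmpl$mass[j], wnt = wnt, notch = notch,
                           divisions = divisions, cycling = TRUE, q = q0,
                           cycle_S = tmpl$S[j, , drop = FALSE],
                           phase = tmpl$phase[j])
    } else {
      world <- append_cell(world, id, type, x, y, z, mass = 1.5,
                           wnt = wnt, notch = notch,
                           divisions = divisions, cycling = FALSE)
    }
    world
  }

  # --- niche cap: checkerboard of stem and Paneth cells; ring layout
  # scales with the niche radius
  dth <- 0.85 / R
  thetas <- seq(dth * 0.45, pi / 2 - 0.08, by = dth)
  cap_rings <- lapply(thetas, function(th)
    list(theta = th, n = max(1L, round(2 * pi * R * sin(th) / 0.85))))
  parity <- 0L
  for (ring in cap_rings) {
    th <- ring$theta
    for (i in seq_len(ring$n)) {
      phi <- 2 * pi * (i - 1) / ring$n + 0.15 * parity
      x <- R * sin(th) * cos(phi); y <- R * sin(th) * sin(phi)
      z <- -R * cos(th)
      type <- if ((i + parity) %% 2L == 0L) CT_PANETH else CT_STEM
      wnt <- config$fate$wnt_high * 2.2
      notch <- if (type == CT_STEM) 1.5 else 0.2
      world <- add(world, type, x, y, z, wnt, notch, niche_cell = TRUE)
    }
    parity <- parity + 1L
  }

  # --- cylinder: progenitors below, mature cells above
  n_ring <- max(6L, round(2 * pi * R))
  ring_dz <- 0.95
  zs <- seq(ring_dz / 2, H - 0.2, by = ring_dz)
  for (j in seq_along(zs)) {
    z <- zs[j]
    for (i in seq_len(n_ring)) {
      phi <- 2 * pi * (i - 1) / n_ring + (j %% 2L) * pi / n_ring
      x <- R * cos(phi); y <- R * sin(phi)
      wnt <- config$fate$wnt_high * 0.8 * 2^(-(z / 1.5))
      if (z <= 6) {
        divisions <- min(config$fate$max_divisions - 1L,
                         as.integer(floor(z / 1.6)))
        if (i %% 7L == 0L) {
          world <- add(world, CT_SECRETORY_PROGENITOR, x, y, z, wnt, 0.2,
                       divisions)
        } else {
          world <- add(world, CT_ABSORPTIVE_PROGENITOR, x, y, z, wnt, 1.2,
                       divisions)
        }
      } else {
        type <- if (i %% 8L == 0L) CT_GOBLET else
          if (i %% 23L == 0L) CT_ENTEROENDOCRINE else CT_ENTEROCYTE
        world <- add(world, type, x, y, z, wnt, 0.4)
      }
    }
  }

  # --- villus: pre-filled conveyor at the homeostatic ratio
  n_crypt <- length(world$cells$id)
  nv <- round(geom$villus_ratio * n_crypt)
  vt <- sample(c(CT_ENTEROCYTE, CT_GOBLET, CT_ENTEROENDOCRINE), nv,
               replace = TRUE, prob = c(0.90, 0.08, 0.02))
  n_ap <- sum(world$cells$type == CT_ABSORPTIVE_PROGENITOR)
  influx <- n_ap / config$cycle$period_T0 +
    sum(world$cells$type == CT_STEM) / 21.5
  transit <- nv / max(influx, 1e-6)
  world$villus <- villus_init(vt, world$time - transit * (nv:1) / nv,
                              transit_h = transit)
  world
}

# One settled period of the network at p27 production rate q, sampled on
# a grid; used to stagger initial cycle states.
cycle_template <- function(pars, q = 0.05) {
  st <- list(S = cycle_state_init(1L, q, pars), phase = 1L, mass = 1,
             b_entry = NA_real_, cycle_start = 0)
  dt <- 0.05
  keepS <- list(); keep_phase <- integer(0); keep_mass <- numeric(0)
  ndiv <- 0L; t <- 0
  while (t < 150 && ndiv < 3L) {
    st <- integrate_cycle(st, dt, list(q = q), pars, t = t,
                          substeps = 1L)
    if (st$divided) { ndiv <- ndiv + 1L; st$mass <- st$mass / 2 }
    if (ndiv == 2L) {
      keepS[[length(keepS) + 1L]] <- st$S[1L, ]
      keep_phase <- c(keep_phase, st$phase)
      keep_mass <- c(keep_mass, st$mass)
    }
    t <- t + dt
  }
  if (!length(keepS)) stop("cycle template generation failed")
  list(S = do.call(rbind, keepS), phase = keep_phase, mass = keep_mass)
}

#' Advance the world by one step
#'
#' Update order within a tick: drug schedules and PK -> damage
#' accumulation -> signalling fields (Wnt, Notch) -> per-cell cycle ODEs
#' (with checkpoint decisions at phase boundaries) -> divisions and deaths
#' -> fate decisions (including ablation) -> mechanics relaxation ->
#' villus transfer and shedding -> observers.
#'
#' @param world A `WorldState`.
#' @param dt Step (h); defaults to `config$run$dt`.
#' @return The updated world.
#' @export
step <- function(world, dt = world$config$run$dt) {
  stopifnot(dt > 0)
  cfg <- world$config
  t <- world$time

  # 1. schedules + PK
  world$pk <- integrate_pk(world$pk, world$schedule$doses, dt, t,
                           cfg$pharmacology)
  cdk1_strength <- cdk1_schedule(t, world$schedule$cdk1)
  cdk1_on <- cdk1_strength > 0

  # 2. drug-induced damage (uses the current phase annotation)
  world <- accumulate_damage(world, dt)

  # smoothed stem count sensed by the ZNRF3-like feedback (receptor
  # turnover is not instantaneous)
  sc <- sum(world$cells$type == CT_STEM & !world$cells$apoptotic)
  tau <- world$config$signalling$feedback_tau %||% 6
  prev <- world$stats$stem_count_avg %||% sc
  world$stats$stem_count_avg <- prev + (sc - prev) * min(1, dt / tau)

  # 3. signalling
  world <- update_wnt(world, dt,
                      feedback = !isTRUE(cfg$signalling$feedback_off))
  world <- update_notch(world, dt)

  # 4. pressure -> p27 production; damage coupling; arrests
  cl <- world$cells
  n <- length(cl$id)
  if (n) {
    pr <- pressure(world)
    q <- couple_pressure(pr, cfg$cycle)
    sp <- cl$type == CT_SECRETORY_PROGENITOR
    q[sp] <- pmax(q[sp], cfg$fate$sp_q_slow)
    world$cycle$q <- q
    dmg <- apply_damage_coupling(cl$dna, cl$rna, cfg$cycle)
    # p21-pool arrest: sustained sub-lethal DNA damage eventually stops
    # the cycle (the pool builds slowly, so lethally damaged cells reach
    # their G2/M checkpoint first)
    p21_pool_arrest <- world$cycle$S[, "p21"] > cfg$cycle$p21_arrest
    newly_arrested <- which((dmg$arrest | p21_pool_arrest) & cl$cycling &
                              !cl$apoptotic & !cl$arrested)
    if (length(newly_arrested)) {
      cl$arrested[newly_arrested] <- TRUE
      cl$arrest_time[newly_arrested] <- t
      cl$cycling[newly_arrested] <- FALSE
      world$cells <- cl
      for (k in newly_arrested) {
        world <- log_event(world, "arrest", cl$id[k], cl$type[k],
                           detail = "damage")
      }
      cl <- world$cells
    }

    # 5. cycle ODEs for active proliferative cells
    act <- which(cl$cycling & !cl$apoptotic & !cl$arrested &
                   !world$cycle$frozen)
    if (length(act)) {
      st <- list(S = world$cycle$S[act, , drop = FALSE],
                 phase = world$cycle$phase[act],
                 mass = cl$mass[act],
                 b_entry = world$cycle$b_entry[act],
                 cycle_start = world$cycle$cycle_start[act],
                 mass_target = world$cycle$mass_target[act],
                 frozen = world$cycle$frozen[act])
      pert <- list(q = world$cycle$q[act],
                   sigma = dmg$sigma[act],
                   p21_prod = dmg$p21_prod[act],
                   rho = if (cdk1_on) 1 - cfg$pharmacology$cdk1_strength
                   else 1,
                   cdk1_active = cdk1_on,
                   death_draws = if (cdk1_on) stats::runif(length(act))
                   else 0)
      st <- integrate_cycle(st, dt, pert, cfg$cycle, t = t)
      world$cycle$S[act, ] <- st$S
      world$cycle$phase[act] <- st$phase
      world$cycle$b_entry[act] <- st$b_entry
      world$cycle$cycle_start[act] <- st$cycle_start
      world$cycle$mass_target[act] <- st$mass_target
      world$cycle$frozen[act] <- st$frozen
      cl$mass[act] <- st$mass
      cl$radius[act] <- radius_from_mass(st$mass, cl$type[act], cfg)
      # Ki-67 memory: last time seen cycling outside G1
      non_g1 <- act[st$phase != 1L]
      cl$ki67_memory[non_g1] <- t + dt
      world$cells <- cl

      # checkpoint decisions at G1/S and G2/M boundaries
      bnd <- act[st$entered_s | st$entered_m]
      if (length(bnd)) {
        dec <- checkpoint_decision(cl$dna[bnd], cl$rna[bnd],
                                   cfg$pharmacology, cfg$cycle)
        die <- bnd[dec == "APOPTOSIS"]
        if (length(die)) world <- mark_death(world, die, "apoptosis")
      }
      # mitotic deaths under CDK1 inhibition (the severity criterion
      # gates eligibility; the death lottery ran inside the integrator)
      md <- act[st$mitotic_death]
      if (length(md)) world <- mark_death(world, md, "mitotic_death")
      # premature G1 restarts: log; oversized cells arrest as giants
      rs <- act[st$restarted]
      if (length(rs)) {
        for (k in rs) {
          world <- log_event(world, "cycle_restart", world$cells$id[k],
                             world$cells$type[k])
        }
      }
      cl <- world$cells
      big <- which(cl$cycling & cl$mass >= cfg$cycle$giant_mass)
      if (length(big)) {
        cl$giant[big] <- TRUE
        cl$arrested[big] <- TRUE
        cl$arrest_time[big] <- t
        cl$cycling[big] <- FALSE
        world$cells <- cl
        for (k in big) {
          world <- log_event(world, "giant_arrest", cl$id[k], cl$type[k])
        }
        cl <- world$cells
      }

      # divisions
      div <- act[st$divided]
      div <- div[!cl$apoptotic[div] & !cl$arrested[div]]
      if (length(div)) {
        world <- record_division_stats(world, div)
        mother_ids <- cl$id[div]
        for (id in mother_ids) {
          k <- match(id, world$cells$id)
          world <- log_event(world, "division", id, world$cells$type[k])
          world$cells$last_division_time[k] <- t + dt
          world <- add_daughters(world, k)
          world <- remove_cells(world, match(id, world$cells$id))
        }
      }
    }
  }

  # BrdU pulse labelling: S-phase cells during an active pulse window
  world <- apply_brdu_pulse(world)

  # 6. fate decisions and ablation
  if (!is.null(world$schedule$ablation)) {
    world <- ablate_stem(world, world$schedule$ablation)
  }
  world <- decide_fate(world)

  # clear apoptotic cells past the clearance delay
  gone <- which(world$cells$apoptotic &
                  t - world$cells$apopt_since >=
                  cfg$fate$clearance_delay)
  if (length(gone)) {
    for (k in gone) {
      world <- log_event(world, world$cells$death_cause[k],
                         world$cells$id[k], world$cells$type[k])
    }
    world <- remove_cells(world, gone)
  }

  # 7. mechanics
  world <- relax(world, dt)

  # purity flags for cycle-duration statistics
  cl <- world$cells
  stem <- cl$type == CT_STEM
  ap <- cl$type == CT_ABSORPTIVE_PROGENITOR
  cl$pure_region[stem & cl$z > 0] <- FALSE
  cl$pure_region[ap & cl$z <= 0] <- FALSE
  world$cells <- cl

  # crowding-induced live-cell extrusion above the niche: severely
  # compressed cells are shed into the lumen
  mech <- cfg$mechanics
  if (!is.null(mech$extrusion_pressure) && length(world$cells$id)) {
    prx <- pressure(world)
    cand <- which(prx > mech$extrusion_pressure &
                    world$cells$z > mech$extrusion_zmin &
                    !world$cells$apoptotic)
    if (length(cand)) {
      go <- cand[stats::runif(length(cand)) < mech$extrusion_rate * dt]
      if (length(go)) {
        for (k in go) {
          world <- log_event(world, "shedding", world$cells$id[k],
                             world$cells$type[k], detail = "extrusion")
        }
        world <- remove_cells(world, go)
      }
    }
  }

  # 8. villus
  world <- transfer_and_shed(world, dt)

  # 9. observers
  world$time <- t + dt
  if (world$time - world$obs$last_record >=
      cfg$run$record_interval - 1e-9) {
    world <- record_observation(world)
    world$obs$last_record <- world$time
  }
  world
}

record_division_stats <- function(world, rows) {
  cl <- world$cells
  t <- world$time
  for (k in rows) {
    iv <- t - cl$birth_time[k]
    if (cl$pure_type[k] && cl$pure_region[k]) {
      if (cl$type[k] == CT_STEM) {
        world$stats$stem_intervals <- c(world$stats$stem_intervals, iv)
        world$stats$stem_times <- c(world$stats$stem_times, t)
      } else if (cl$type[k] == CT_ABSORPTIVE_PROGENITOR) {
        world$stats$ta_intervals <- c(world$stats$ta_intervals, iv)
        world$stats$ta_times <- c(world$stats$ta_times, t)
      }
    }
  }
  world
}

apply_brdu_pulse <- function(world) {
  pulses <- world$schedule$brdu_pulses
  if (is.null(pulses) || !length(pulses)) return(world)
  t <- world$time
  active <- any(t >= pulses & t <= pulses + 2)  # 120 min window
  if (!active) return(world)
  in_s <- world$cells$cycling & !world$cells$apoptotic &
    world$cycle$phase == 2L
  world$cells$brdu[in_s] <- 1
  world
}

record_observation <- function(world) {
  cnt <- count_types(world)
  ki <- sum(ki67_positive(world))
  row <- c(list(time = world$time,
                crypt_total = sum(!world$cells$apoptotic),
                villus_total = length(world$villus$type),
                villus_enterocytes = villus_enterocyte_count(world),
                ki67 = ki),
           as.list(cnt))
  world$obs$counts[[length(world$obs$counts) + 1L]] <- row
  co <- surface_coords(cell_xyz(world), world$config$geometry)
  world$obs$traj[[length(world$obs$traj) + 1L]] <-
    list(time = world$time, id = world$cells$id, z = co$z,
         theta = co$theta, s = co$s)
  world
}

#' Observed counts as a data frame
#'
#' One row per observer record (cadence `run$record_interval`).
#'
#' @param world A `WorldState`.
#' @return Data frame of counts over time.
#' @export
counts_frame <- function(world) {
  do.call(rbind, lapply(world$obs$counts, function(r)
    as.data.frame(r, check.names = FALSE)))
}

#' Run a world for a duration
#'
#' @param world A `WorldState`.
#' @param hours Duration (h).
#' @param dt Step; defaults to the configured step.
#' @return Updated world.
#' @export
run_world <- function(world, hours, dt = world$config$run$dt) {
  nsteps <- round(hours / dt)
  for (i in seq_len(nsteps)) world <- step(world, dt)
  world
}
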