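# Deterministic miniature fixtures ------------------------------------------
#
# Named generators for tiny worlds and synthetic trajectory sets, pure
# functions of (name, seed), so every module can be tested in milliseconds
# without running full simulations.  Fixtures live in the package (not
# test-only) so the command-line tools can run demo scenarios on them.

#' Miniature configuration used by fixtures
#'
#' A reduced crypt (radius 1.1, height 4) holding well under 40 cells.
#'
#' @return Configuration list.
#' @export
fixture_config <- function() {
  cfg <- default_config()
  cfg$geometry$radius <- 1.1
  cfg$geometry$height <- 4
  cfg$signalling$n_star <- 6
  cfg$signalling$bmp_z_half <- 2
  cfg
}

empty_world <- function(config) {
  validate_config(config)
  list(
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
}

fixture_add <- function(world, type, x, y, z, wnt = 0, notch = 0,
                        brdu = 0, divisions = 0L, mass = 1.5) {
  id <- world$next_id
  world$next_id <- world$next_id + 1L
  p <- surface_project(matrix(c(x, y, z), 1L), world$config$geometry)
  append_cell(world, id, type, p[1L], p[2L], p[3L], mass = mass,
              wnt = wnt, notch = notch, brdu = brdu,
              divisions = divisions)
}

#' Build a named fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{checkerboard_niche}{Stem and Paneth cells intermingled in the
#'     on-off pattern on the hemispherical cap (sparse Paneth among
#'     Notch-active stem cells), with a few absorptive progenitors above
#'     the rim.}
#'   \item{overlap_pair}{Two equal cells on the cylinder wall with 20\%
#'     radius overlap; the spring force is known in closed form.}
#'   \item{paneth_stem_pair}{Overlapping Paneth-stem pair (Paneth stiffer
#'     and larger).}
#'   \item{staining_columns}{Two hemi-crypt columns of 10 cells each with
#'     a prescribed BrdU-positive set: positions 1-3 in the first column,
#'     positions 2 and 4 in the second.}
#'   \item{conveyor_villus}{A crypt with cells near the mouth and a
#'     pre-filled villus conveyor.}
#'   \item{trajectory_pair}{Two cells with prescribed recorded tracks: one
#'     moving up, one moving down, at the same position bin.}
#'   \item{mini_crypt}{A complete miniature crypt (under 40 cells) built
#'     by [initialize_world()] on [fixture_config()].}
#' }
#'
#' @param name Fixture name.
#' @param seed RNG seed.
#' @return A `WorldState`.
#' @export
make_fixture <- function(name, seed = 1) {
  set.seed(seed)
  cfg <- fixture_config()
  switch(
    name,
    checkerboard_niche = {
      # full-size niche so Paneth cells sit isolated among stems, as in
      # the homeostatic pattern
      cfg2 <- cfg
      cfg2$geometry$radius <- 2
      w <- empty_world(cfg2)
      R <- 2
      rings <- list(list(theta = 0.35, n = 5), list(theta = 0.85, n = 9),
                    list(theta = 1.35, n = 13))
      parity <- 0L
      for (ring in rings) {
        for (i in seq_len(ring$n)) {
          phi <- 2 * pi * (i - 1) / ring$n
          x <- R * sin(ring$theta) * cos(phi)
          y <- R * sin(ring$theta) * sin(phi)
          z <- -R * cos(ring$theta)
          type <- if ((i + parity) %% 3L == 0L) CT_PANETH else CT_STEM
          w <- fixture_add(w, type, x, y, z,
                           wnt = cfg$fate$wnt_high * 1.5,
                           notch = if (type == CT_STEM) 1.5 else 0.2)
        }
        parity <- parity + 1L
      }
      for (i in 1:6) {
        phi <- 2 * pi * (i - 1) / 6
        w <- fixture_add(w, CT_ABSORPTIVE_PROGENITOR,
                         R * cos(phi), R * sin(phi), 0.8,
                         wnt = 4, notch = 1.2)
      }
      w
    },
    overlap_pair = {
      w <- empty_world(cfg)
      # 20% radius overlap: centre distance = 0.8 * (r1 + r2)
      r <- radius_from_mass(1.5, CT_STEM, cfg)
      d <- 0.8 * 2 * r
      R <- cfg$geometry$radius
      dphi <- d / R
      w <- fixture_add(w, CT_STEM, R, 0, 1.0)
      w <- fixture_add(w, CT_STEM, R * cos(dphi), R * sin(dphi), 1.0)
      w
    },
    paneth_stem_pair = {
      w <- empty_world(cfg)
      R <- cfg$geometry$radius
      rp <- radius_from_mass(1.5, CT_PANETH, cfg)
      rs <- radius_from_mass(1.5, CT_STEM, cfg)
      d <- 0.8 * (rp + rs)
      dphi <- d / R
      w <- fixture_add(w, CT_PANETH, R, 0, 1.0)
      w <- fixture_add(w, CT_STEM, R * cos(dphi), R * sin(dphi), 1.0)
      w
    },
    staining_columns = {
      cfg2 <- cfg
      cfg2$geometry$height <- 10
      w <- empty_world(cfg2)
      R <- cfg2$geometry$radius
      lab1 <- c(1, 2, 3); lab2 <- c(2, 4)
      for (p in 1:10) {
        z <- -R + 0.001 + (p - 1) * (10 + R) / 10 + R  # spread along axis
        z <- (p - 1) * 1.0 + 0.3
        w <- fixture_add(w, CT_ABSORPTIVE_PROGENITOR, R, 0.01, z,
                         brdu = if (p %in% lab1) 1 else 0)
        w <- fixture_add(w, CT_ABSORPTIVE_PROGENITOR, -R, -0.01, z,
                         brdu = if (p %in% lab2) 1 else 0)
      }
      w
    },
    conveyor_villus = {
      w <- empty_world(cfg)
      R <- cfg$geometry$radius; H <- cfg$geometry$height
      for (i in 1:6) {
        phi <- 2 * pi * (i - 1) / 6
        w <- fixture_add(w, CT_ENTEROCYTE, R * cos(phi), R * sin(phi),
                         H - 0.2)
      }
      w$villus <- villus_init(rep(CT_ENTEROCYTE, 20),
                              -(20:1) / 2, transit_h = 10)
      w
    },
    trajectory_pair = {
      w <- empty_world(cfg)
      R <- cfg$geometry$radius
      w <- fixture_add(w, CT_ABSORPTIVE_PROGENITOR, R, 0.01, 2.0)
      w <- fixture_add(w, CT_ABSORPTIVE_PROGENITOR, -R, -0.01, 2.0)
      # prescribed tracks over one hour: cell 1 up, cell 2 down
      for (i in 0:2) {
        t <- i * 0.5
        z1 <- 2.0 + 0.3 * i; z2 <- 2.0 - 0.3 * i
        th <- pi / 2
        s0 <- R * pi / 2
        w$obs$traj[[i + 1L]] <- list(
          time = t, id = c(1L, 2L), z = c(z1, z2),
          theta = c(th, th), s = c(s0 + z1, s0 + z2))
      }
      w$time <- 1.0
      w
    },
    mini_crypt = {
      cfg$run$seed <- seed
      initialize_world(cfg)
    },
    stop("unknown fixture: ", name,
         " (known: checkerboard_niche, overlap_pair, paneth_stem_pair, ",
         "staining_columns, conveyor_villus, trajectory_pair, mini_crypt)")
  )
}

#' List available fixtures
#'
#' @return Character vector of fixture names.
#' @export
list_fixtures <- function() {
  c("checkerboard_niche", "overlap_pair", "paneth_stem_pair",
    "staining_columns", "conveyor_villus", "trajectory_pair", "mini_crypt")
}
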