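# Simulation configuration -------------------------------------------------

#' Default simulation configuration
#'
#' Returns the full parameter set of the model as a nested named list.
#' Every constant used anywhere in the simulation lives here; scenario
#' definitions override entries of this list.  Time is in hours throughout;
#' lengths are in cell-diameter units internally (`geometry$cell_diameter_um`
#' converts to micrometres at I/O boundaries).
#'
#' Sections:
#' \describe{
#'   \item{geometry}{`radius` of the hemispherical niche and crypt cylinder,
#'     cylinder `height` (crypt mouth at `z = height`), `villus_ratio`
#'     (homeostatic villus cell count as a multiple of crypt cell count).}
#'   \item{mechanics}{Hookean overlap-spring constant `k_spring` (force per
#'     unit overlap, per unit drag), `contact_factor` on the sum of radii,
#'     Paneth radius and stiffness factors, division separation, and the
#'     mechanical sub-step `dt_mech`.}
#'   \item{signalling}{Wnt emission range and tethering rate, the ZNRF3-like
#'     feedback (`n_star` homeostatic stem count, Hill coefficient
#'     `h_feedback`), Notch accumulation/decay, and the BMP profile
#'     (enterocyte-count coupling, logistic profile in z, niche antagonist
#'     zone).}
#'   \item{fate}{Wnt/Notch thresholds of the fate rules, the BMP-vs-Wnt
#'     terminal-differentiation trade-off, the progenitor division band,
#'     the goblet:enteroendocrine maturation split, and the dwell time that
#'     debounces type switches.}
#'   \item{cycle}{Cell-cycle network constants, see [cycle_params()].}
#'   \item{pharmacology}{5-FU PK constants, damage/repair rates, checkpoint
#'     thresholds, CDK1-inhibitor strength.}
#'   \item{run}{Global step `dt` (h), RNG `seed`, observer `record_interval`.}
#' }
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(
      radius = 2.0,            # niche hemisphere / crypt cylinder radius
      height = 14,             # crypt mouth at z = height
      cell_diameter_um = 10,   # one internal length unit in micrometres
      villus_ratio = 3.5,      # villus cells per crypt cell in homeostasis
      include_crypt_enterocytes = TRUE  # count crypt-resident mature
                               # enterocytes in the BMP-driving E(t)
    ),
    mechanics = list(
      k_spring = 130,          # overlap spring constant / drag (per hour)
      contact_factor = 1.0,    # neighbours if dist < factor * (r_i + r_j)
      k_adhesion = 10,         # short-range adhesion strength
      paneth_rest_factor = 0.80, # rest length of Paneth contacts
                               # (interdigitated interfaces)
      paneth_anchor = 6,       # extra drag factor anchoring Paneth cells
                               # at the crypt base
      adhesion_range = 1.15,   # adhesive reach as multiple of r_i + r_j
      paneth_radius_factor = 1.50,
      paneth_stiffness_factor = 5,
      division_sep = 0.30,     # daughter offset along a random tangent
      dt_mech = 0.001,         # mechanical sub-step (h)
      max_disp = 0.5,          # abort if a cell moves farther per sub-step
      extrusion_pressure = 99, # live-cell extrusion above this pressure
      extrusion_rate = 1.0,    # extrusion hazard (per h) when compressed
      extrusion_zmin = 1.0     # extrusion only above the niche
    ),
    signalling = list(
      r_wnt = 1.4,             # emission range of Wnt sources
      k_tether = 0.8,          # tethering rate per source in range (A.U./h)
      paneth_emission = 3,     # ligand budget per Paneth cell (kernel sum)
      src_cap = 3,             # receptor-limited cap on the summed source
                               # kernel a cell can engage
      n_star = 12,             # homeostatic stem count (ZNRF3 feedback)
      h_feedback = 1,          # feedback Hill exponent (>= 1)
      feedback_tau = 8,        # smoothing time of the sensed stem count (h)
      mesench_theta = 30,      # polar angle (deg) of the mesenchymal ring
      k_notch = 0.5,           # Notch accumulation per Delta presenter (/h)
      lambda_notch = 0.5,      # Notch first-order decay (/h)
      bmp_beta = 2.5e-2,       # BMP scale per enterocyte
      bmp_z_half = 4,          # logistic profile midpoint (z)
      bmp_width = 2,           # logistic profile width (z)
      bmp_antagonist_zone = 1.0, # a(z) < 1 for z below this
      bmp_a_min = 0.1          # antagonist suppression factor
    ),
    fate = list(
      wnt_high = 7,            # stemness Wnt threshold
      wnt_low = 2,             # niche-exit Wnt level (secretory maturation)
      notch_on = 0.8,          # Notch activation threshold
      dediff_wnt_factor = 2.6, # reprogramming to STEM needs wnt above
                               # dediff_wnt_factor * wnt_high (hysteresis)
      paneth_wnt_factor = 1.2, # Paneth fate needs wnt above
                               # paneth_wnt_factor * wnt_high (deep niche)
      alpha = 1.0,             # terminal differentiation: B > alpha*wnt+beta
      beta = 0.5,
      cap_bmp_floor = 0.15,    # the forced division cap needs at least
                               # this much BMP (relay collapse suspends it)
      min_divisions = 3,       # absorptive progenitors divide 3..5 times
      max_divisions = 5,
      goblet_fraction = 0.75,  # goblet : enteroendocrine split
      dwell = 0.5,             # h a fate decision must persist to take effect
      sp_q_slow = 0.25,        # minimum p27 production of secretory prog.
      clearance_delay = 1.0,   # h from apoptosis to removal
      maturation_delay = 2.0,  # h outside niche before secretory maturation
      stem_exit_dwell = 2,     # h a stem must hold sub-threshold signals
                               # before committing (no flicker commitment)
      stem_dediff_dwell = 8,   # h of sustained stem-level signals before
                               # a progenitor reprograms to STEM
      paneth_diff_dwell = 4,   # h of sustained Notch-off before a stem
                               # commits to the Paneth fate
      paneth_dediff_dwell = 9  # h of sustained stem-level signals before a
                               # Paneth cell reprograms to STEM
    ),
    cycle = cycle_params(),
    pharmacology = list(
      pk_scale = 500,          # plasma ng/ml per mg/kg bolus
      epithelium_factor = 1.0, # epithelium-to-plasma concentration ratio
      ke_fu = 3.0,             # 5-FU elimination (/h); short half-life
      fm_futp = 0.4, fm_fdump = 0.3, fm_fdutp = 0.2,   # formation (/h)
      ke_futp = 0.7, ke_fdump = 0.8, ke_fdutp = 0.9,   # elimination (/h)
      k_dna = 8.5e-4,          # DNA damage per (ng/ml FdUTP) h, S-phase only
      k_rna = 4e-5,            # RNA damage per (ng/ml FUTP) h, proliferative
      repair_dna = 0.05,       # repair (/h)
      repair_rna = 0.10,
      th_apopt_dna = 1.0,      # checkpoint apoptosis thresholds
      th_apopt_rna = 1.0,
      cdk1_strength = 0.95     # CDK1-inhibitor production suppression
    ),
    observers = list(
      ki67_g1_positive = FALSE, # TRUE: cycling cells stain in G1 too
      th_brdu = 0.04,          # detection threshold, between 1/32 and 1/16
      ki67_memory_h = 6,       # staining memory after differentiation/arrest
      sectors = 2              # hemi-crypt columns per crypt
    ),
    run = list(
      dt = 0.05,               # global step (h)
      seed = 1,
      record_interval = 0.5,   # observer cadence (h)
      burn_in_days = 5         # scenario burn-in before interventions
    )
  )
}

#' Validate a simulation configuration
#'
#' Checks positivity/range constraints on the configuration; called by
#' [initialize_world()].
#'
#' @param config Nested list as returned by [default_config()].
#' @return The config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  g <- config$geometry
  if (!is.numeric(g$radius) || g$radius <= 0 ||
      !is.numeric(g$height) || g$height <= 0) {
    stop("invalid geometry: radius and height must be positive")
  }
  rates <- c(
    unlist(config$mechanics), unlist(config$signalling),
    unlist(config$pharmacology), config$fate$dwell,
    config$run$record_interval
  )
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates and constants must be finite and non-negative")
  }
  if (config$run$dt <= 0) stop("run$dt must be > 0")
  if (config$fate$wnt_high <= config$fate$wnt_low) {
    stop("fate thresholds must satisfy wnt_high > wnt_low")
  }
  invisible(config)
}

#' Merge configuration overrides
#'
#' Recursively merges `overrides` into `base`, replacing leaves.
#'
#' @param base,overrides Nested lists.
#' @return Merged nested list.
#' @export
merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read / write configuration as YAML
#'
#' Round-trip safe: `read_config(write_config(cfg, f))` returns an
#' identical configuration.
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}
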