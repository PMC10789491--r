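# Cell-fate decision rules ---------------------------------------------------
#
# Fate is re-evaluated continuously (every tick) from the cell's current
# tethered Wnt, Notch activation, BMP level and division count, which makes
# all decisions reversible by construction.  A short dwell requirement
# debounces threshold chatter.  Dedifferentiation into the stem state is
# the same rule set applied to the plastic types, and is logged with the
# originating type.

#' Target fate for given signal levels
#'
#' The quadrant rules over (Wnt, Notch):
#' high Wnt + Notch on -> STEM; high Wnt + Notch off -> PANETH;
#' low Wnt + Notch on -> ABSORPTIVE_PROGENITOR; low Wnt + Notch off ->
#' SECRETORY_PROGENITOR.  These four rules are mutually exclusive and
#' exhaustive.  Terminal transitions are layered on top: an absorptive
#' progenitor whose BMP exceeds `alpha * wnt + beta` after at least
#' `min_divisions` divisions (unconditionally after `max_divisions`)
#' becomes an ENTEROCYTE; a secretory progenitor that has left the niche
#' matures to GOBLET or ENTEROENDOCRINE.
#'
#' Mature cells are not remapped by the quadrant rules unless they belong
#' to the plastic set (`PANETH`), in which case regaining stem-level Wnt
#' and Notch reverts them to STEM (dedifferentiation).
#'
#' @param type Current cell type code.
#' @param wnt,notch Signal levels (A.U.).
#' @param bmp BMP level at the cell position (A.U.).
#' @param divisions Completed divisions since commitment.
#' @param fate Fate section of the configuration.
#' @return Target type code (may equal `type`).
#' @export
fate_target <- function(type, wnt, notch, bmp, divisions, fate) {
  wnt_hi <- wnt >= fate$wnt_high
  notch_on <- notch >= fate$notch_on
  wnt_paneth <- wnt >= fate$paneth_wnt_factor * fate$wnt_high
  quadrant <- if (wnt_hi && notch_on) CT_STEM
  else if (wnt_paneth && !notch_on) CT_PANETH
  else if (notch_on) CT_ABSORPTIVE_PROGENITOR
  else CT_SECRETORY_PROGENITOR

  if (type %in% c(CT_STEM, CT_ABSORPTIVE_PROGENITOR,
                  CT_SECRETORY_PROGENITOR)) {
    if (type == CT_ABSORPTIVE_PROGENITOR && quadrant == CT_PANETH) {
      quadrant <- CT_SECRETORY_PROGENITOR
    }
    if (type == CT_ABSORPTIVE_PROGENITOR && quadrant != CT_STEM) {
      # terminal differentiation by the BMP-vs-Wnt trade-off
      if ((divisions >= fate$max_divisions &&
           bmp > fate$cap_bmp_floor) ||
          (divisions >= fate$min_divisions &&
           bmp > fate$alpha * wnt + fate$beta)) {
        return(CT_ENTEROCYTE)
      }
    }
    return(quadrant)
  }
  if (type == CT_PANETH) {
    # plastic: reverts to STEM on regaining stem-level signals
    if (quadrant == CT_STEM) return(CT_STEM)
    return(CT_PANETH)
  }
  # goblet, enteroendocrine, enterocytes: terminally differentiated here
  type
}

#' Apply fate decisions to every cell
#'
#' Computes the target fate of each non-apoptotic cell (vectorized) and
#' commits a type switch once the same target has persisted for the
#' configured dwell time.  Secretory progenitors outside the niche mature
#' to goblet or enteroendocrine cells (configured split, drawn once when
#' the maturation first becomes pending) after `maturation_delay`.  Type
#' switches into STEM from the plastic set are logged as dedifferentiation
#' with the originating type; all others as fate events.
#'
#' @param world A `WorldState`.
#' @return Updated world.
#' @export
decide_fate <- function(world) {
  cl <- world$cells
  n <- length(cl$x)
  if (n == 0L) return(world)
  fate <- world$config$fate
  now <- world$time
  bmp <- evaluate_bmp(world, cl$z)

  wnt_hi <- cl$wnt >= fate$wnt_high
  notch_on <- cl$notch >= fate$notch_on
  # Paneth differentiation requires the deepest (Wnt-richest) niche
  # environment; Notch-off cells below that bar take the (slow-cycling)
  # secretory-progenitor fate
  wnt_paneth <- cl$wnt >= fate$paneth_wnt_factor * fate$wnt_high
  quadrant <- ifelse(wnt_hi & notch_on, CT_STEM,
              ifelse(wnt_paneth & !notch_on, CT_PANETH,
              ifelse(notch_on, CT_ABSORPTIVE_PROGENITOR,
                     CT_SECRETORY_PROGENITOR)))
  tgt <- cl$type
  prog <- cl$type %in% c(CT_STEM, CT_ABSORPTIVE_PROGENITOR,
                         CT_SECRETORY_PROGENITOR)
  tgt[prog] <- quadrant[prog]
  # the Paneth fate is open to stem cells and secretory progenitors
  # (secretory commitment in high-Wnt regions); absorptive progenitors
  # first take the secretory fate
  ap_pan <- cl$type == CT_ABSORPTIVE_PROGENITOR & tgt == CT_PANETH
  tgt[ap_pan] <- CT_SECRETORY_PROGENITOR
  # dedifferentiation hysteresis: a committed cell reprograms to STEM
  # only on regaining well above maintenance-level Wnt
  dediff_bar <- fate$dediff_wnt_factor * fate$wnt_high
  no_dediff <- cl$type != CT_STEM & tgt == CT_STEM & cl$wnt < dediff_bar
  tgt[no_dediff] <- cl$type[no_dediff]
  # terminal differentiation of absorptive progenitors; the forced cap
  # at the top of the division band applies only where BMP is present --
  # in the niche antagonist zone and after epithelial damage collapses
  # the relay, progenitors keep dividing (the regeneration reservoir)
  ap <- cl$type == CT_ABSORPTIVE_PROGENITOR & quadrant != CT_STEM &
    ((cl$divisions >= fate$max_divisions & bmp > fate$cap_bmp_floor) |
       (cl$divisions >= fate$min_divisions &
          bmp > fate$alpha * cl$wnt + fate$beta))
  tgt[ap] <- CT_ENTEROCYTE
  # Paneth plasticity
  pan <- cl$type == CT_PANETH
  tgt[pan] <- ifelse(quadrant[pan] == CT_STEM, CT_STEM, CT_PANETH)
  # secretory progenitor maturation outside the niche: keep an already
  # pending goblet/enteroendocrine draw, or draw afresh
  sp_mat <- cl$type == CT_SECRETORY_PROGENITOR &
    tgt == CT_SECRETORY_PROGENITOR & cl$z > 0 & cl$wnt < fate$wnt_low
  keep <- sp_mat & !is.na(cl$pending_type) &
    cl$pending_type %in% c(CT_GOBLET, CT_ENTEROENDOCRINE)
  tgt[keep] <- cl$pending_type[keep]
  fresh <- which(sp_mat & !keep)
  if (length(fresh)) {
    draws <- stats::runif(length(fresh))
    tgt[fresh] <- ifelse(draws < fate$goblet_fraction, CT_GOBLET,
                         CT_ENTEROENDOCRINE)
  }
  blocked <- cl$apoptotic | cl$arrested
  tgt[blocked] <- cl$type[blocked]

  same <- tgt == cl$type
  cl$pending_type[same] <- NA_integer_
  cl$pending_since[same] <- NA_real_
  restart <- !same & (is.na(cl$pending_since) | cl$pending_type != tgt |
                        is.na(cl$pending_type))
  cl$pending_type[restart] <- tgt[restart]
  cl$pending_since[restart] <- now
  dwell_needed <- ifelse(tgt %in% c(CT_GOBLET, CT_ENTEROENDOCRINE),
                         fate$maturation_delay, fate$dwell)
  # reprogramming to the stem state requires persistently stem-level
  # signals: progenitors hold them for hours (regeneration), Paneth cells
  # far longer (deep commitment); a passing Notch/Wnt blip does nothing
  dwell_needed[tgt == CT_STEM & cl$type %in%
                 c(CT_ABSORPTIVE_PROGENITOR, CT_SECRETORY_PROGENITOR)] <-
    fate$stem_dediff_dwell
  dwell_needed[cl$type == CT_STEM & tgt %in%
                 c(CT_ABSORPTIVE_PROGENITOR, CT_SECRETORY_PROGENITOR)] <-
    fate$stem_exit_dwell
  dwell_needed[cl$type == CT_PANETH & tgt == CT_STEM] <-
    fate$paneth_dediff_dwell
  # and the Paneth fate itself requires sustained Notch-off, not a dip
  dwell_needed[tgt == CT_PANETH & cl$type != CT_PANETH] <-
    fate$paneth_diff_dwell

  commit <- which(!same & !restart &
                    now - cl$pending_since >= dwell_needed)
  world$cells <- cl
  for (k in commit) world <- switch_type(world, k, tgt[k])
  world
}

# Commit a type switch for cell row k, with event logging and cycle
# bookkeeping.
switch_type <- function(world, k, tgt) {
  cl <- world$cells
  old <- cl$type[k]
  plastic <- c(CT_PANETH, CT_ABSORPTIVE_PROGENITOR, CT_SECRETORY_PROGENITOR)
  ev <- if (tgt == CT_STEM && old %in% plastic) "dedifferentiation"
  else "fate_change"
  world <- log_event(world, ev, cl$id[k], old,
                     detail = paste0(CELL_TYPE_NAMES[old], "->",
                                     CELL_TYPE_NAMES[tgt]))
  cl$type[k] <- tgt
  cl$pending_type[k] <- NA_integer_
  cl$pending_since[k] <- NA_real_
  cl$type_since[k] <- world$time
  cl$pure_type[k] <- FALSE
  was_cycling <- cl$cycling[k]
  now_cycling <- tgt %in% PROLIFERATIVE_TYPES
  if (tgt == CT_STEM || old == CT_STEM) cl$divisions[k] <- 0L
  if (!was_cycling && now_cycling) {
    world$cycle$S[k, ] <- cycle_state_init(1, world$cycle$q[k],
                                           world$config$cycle)
    world$cycle$phase[k] <- 1L
    world$cycle$b_entry[k] <- NA_real_
    world$cycle$cycle_start[k] <- world$time
  }
  if (was_cycling && !now_cycling) {
    cl$differentiation_time[k] <- world$time
  }
  if (old == CT_ABSORPTIVE_PROGENITOR && tgt == CT_ENTEROCYTE) {
    world$stats$ap_final_divisions <-
      c(world$stats$ap_final_divisions, cl$divisions[k])
    world$stats$ap_final_div_times <-
      c(world$stats$ap_final_div_times, world$time)
  }
  cl$cycling[k] <- now_cycling
  # Paneth are larger and stiffer
  cl$stiffness[k] <- if (tgt == CT_PANETH) {
    world$config$mechanics$paneth_stiffness_factor
  } else 1
  cl$radius[k] <- radius_from_mass(cl$mass[k], tgt, world$config)
  world$cells <- cl
  world
}

#' Dedifferentiation rule for a single cell
#'
#' Plastic types (Paneth, absorptive progenitor, secretory progenitor)
#' revert to STEM when both Wnt and Notch are at stem level.  Mature
#' goblet, enteroendocrine and enterocyte cells are outside the plastic
#' set.  This is a pure read-out of the same rules applied by
#' [decide_fate()]; it does not modify the world.
#'
#' @param type Current type code.
#' @param wnt,notch Signal levels.
#' @param fate Fate configuration.
#' @return Target type code.
#' @export
dedifferentiate <- function(type, wnt, notch, fate) {
  plastic <- c(CT_PANETH, CT_ABSORPTIVE_PROGENITOR, CT_SECRETORY_PROGENITOR)
  if (type %in% plastic &&
      wnt >= fate$dediff_wnt_factor * fate$wnt_high &&
      notch >= fate$notch_on) {
    return(CT_STEM)
  }
  type
}

#' Stem-cell ablation schedule
#'
#' Implements targeted conditional ablation: during the first 24 h of the
#' treatment window every stem cell is killed by the end of the day
#' (continuous killing with a short lag, plus a sweep at the 24 h mark);
#' for the remaining days any cell acquiring the STEM type is killed after
#' the same short lag; killing persists for `toxin_clearance` hours (default
#' 5) past the final induction while the toxin decays.  Deaths are logged
#' as `ablation`.
#'
#' @param world A `WorldState`.
#' @param schedule List with `start` (h), `days` (duration), `lag` (h).
#' @return Updated world.
#' @export
ablate_stem <- function(world, schedule) {
  t <- world$time
  clearance <- schedule$toxin_clearance %||% 5.5
  if (t < schedule$start ||
      t > schedule$start + schedule$days * 24 + clearance) {
    return(world)
  }
  cl <- world$cells
  stem <- which(cl$type == CT_STEM & !cl$apoptotic)
  if (!length(stem)) return(world)
  held <- t - cl$type_since[stem]
  kill <- stem[held >= schedule$lag]
  if (t >= schedule$start + 24 - world$config$run$dt) {
    # ablation completed after the first 24 h: sweep all remaining stems
    if (t <= schedule$start + 24 + world$config$run$dt) kill <- stem
  }
  if (length(kill)) {
    world <- mark_death(world, kill, "ablation")
  }
  world
}
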