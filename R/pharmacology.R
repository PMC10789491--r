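# 5-FU pharmacokinetics and damage; CDK1-inhibitor schedule -----------------
#
# The PK model is a linear compartmental cascade: bolus absorption of the
# parent (5-FU) into plasma, first-order elimination, and first-order
# formation/elimination of the three active metabolites FUTP, FdUMP and
# FdUTP.  Because the system is linear and piecewise-autonomous between
# doses, it is advanced with the exact closed-form (exponential) update
# rather than a numerical solver, which makes the trace deterministic and
# exactly linear in the dose.  FdUMP is carried in the state but has no
# downstream effect (thymidylate-synthase inhibition is not modelled).

PK_SPECIES <- c("fu", "futp", "fdump", "fdutp")

pk_init <- function() {
  stats::setNames(numeric(4L), PK_SPECIES)
}

# exact update of  M' = a * C0 * exp(-ke*t) - km * M  over dt
metabolite_step <- function(M0, C0, a, ke, km, dt) {
  if (abs(ke - km) < 1e-9) km <- km * (1 + 1e-6)
  M0 * exp(-km * dt) + a * C0 * (exp(-km * dt) - exp(-ke * dt)) / (ke - km)
}

#' Advance the 5-FU pharmacokinetic state
#'
#' Applies any boluses scheduled in `(t, t + dt]` (each dose adds
#' `dose * pk_scale` ng/ml of parent to plasma) and advances the linear
#' cascade exactly over `dt`.
#'
#' @param pk Named concentration vector (`fu`, `futp`, `fdump`, `fdutp`),
#'   ng/ml.
#' @param dose_schedule Data frame with columns `time` (h) and `dose`
#'   (mg/kg); doses must be non-negative.
#' @param dt Step (h).
#' @param t Time at the start of the step (h).
#' @param pars Pharmacology section of the configuration.
#' @return Updated named concentration vector.
#' @export
integrate_pk <- function(pk, dose_schedule, dt, t, pars) {
  if (!is.null(dose_schedule) && nrow(dose_schedule)) {
    if (any(dose_schedule$dose < 0)) stop("negative dose in schedule")
    due <- dose_schedule$time >= t & dose_schedule$time < t + dt
    if (any(due)) {
      pk["fu"] <- pk["fu"] + sum(dose_schedule$dose[due]) * pars$pk_scale
    }
  }
  C0 <- pk["fu"]
  pk["futp"] <- metabolite_step(pk["futp"], C0, pars$fm_futp,
                                pars$ke_fu, pars$ke_futp, dt)
  pk["fdump"] <- metabolite_step(pk["fdump"], C0, pars$fm_fdump,
                                 pars$ke_fu, pars$ke_fdump, dt)
  pk["fdutp"] <- metabolite_step(pk["fdutp"], C0, pars$fm_fdutp,
                                 pars$ke_fu, pars$ke_fdutp, dt)
  pk["fu"] <- C0 * exp(-pars$ke_fu * dt)
  pk
}

#' Full PK trace for a dose schedule
#'
#' Convenience evaluation of [integrate_pk()] on a regular grid.
#'
#' @inheritParams integrate_pk
#' @param t_max End time (h).
#' @return Data frame with `time` and one column per species (ng/ml).
#' @export
pk_trace <- function(dose_schedule, t_max, dt = 0.05,
                     pars = default_config()$pharmacology) {
  ts <- seq(0, t_max, by = dt)
  pk <- pk_init()
  out <- matrix(0, length(ts), 4L, dimnames = list(NULL, PK_SPECIES))
  for (i in seq_along(ts)[-1L]) {
    pk <- integrate_pk(pk, dose_schedule, dt, ts[i - 1L], pars)
    out[i, ] <- pk
  }
  cbind(data.frame(time = ts), as.data.frame(out))
}

#' Accumulate drug-induced damage in cells
#'
#' FUTP is incorporated into the RNA of proliferative cells (any phase);
#' FdUTP is incorporated into DNA only during S-phase.  Both are repaired
#' first-order.  Non-proliferative cells accumulate nothing and only
#' repair.  Epithelial exposure is plasma concentration times
#' `epithelium_factor`.
#'
#' @param world A `WorldState`.
#' @param dt Step (h).
#' @return Updated world.
#' @export
accumulate_damage <- function(world, dt) {
  ph <- world$config$pharmacology
  cl <- world$cells
  eff <- ph$epithelium_factor
  prolif <- cl$cycling & !cl$apoptotic & !cl$arrested
  in_s <- prolif & world$cycle$phase == 2L
  cl$rna <- pmax(0, cl$rna +
                   (ph$k_rna * eff * world$pk[["futp"]]) * prolif * dt -
                   ph$repair_rna * cl$rna * dt)
  cl$dna <- pmax(0, cl$dna +
                   (ph$k_dna * eff * world$pk[["fdutp"]]) * in_s * dt -
                   ph$repair_dna * cl$dna * dt)
  world$cells <- cl
  world
}

#' Checkpoint decision for a cell at a phase boundary
#'
#' Evaluated when a cell crosses the G1/S or G2/M boundary: APOPTOSIS if
#' DNA or RNA damage exceeds the apoptosis thresholds; otherwise SLOW if
#' DNA damage is above the p21 activation floor (the p21 pathway handled
#' continuously by [apply_damage_coupling()]); otherwise CONTINUE.
#'
#' @param dna_damage,rna_damage Damage levels (A.U.).
#' @param pars Pharmacology configuration.
#' @param cycle_pars Cycle configuration (for the p21 floor).
#' @return One of `"APOPTOSIS"`, `"SLOW"`, `"CONTINUE"` (vectorized).
#' @export
checkpoint_decision <- function(dna_damage, rna_damage,
                                pars = default_config()$pharmacology,
                                cycle_pars = cycle_params()) {
  ifelse(dna_damage >= pars$th_apopt_dna | rna_damage >= pars$th_apopt_rna,
         "APOPTOSIS",
         ifelse(dna_damage >= cycle_pars$th_p21, "SLOW", "CONTINUE"))
}

#' CDK1-inhibitor schedule
#'
#' Pulsed inhibition: active for the first `on_h` hours of every `cycle_h`
#' window, for `days` consecutive days from `start`; returns the
#' configured strength while active, otherwise 0.
#'
#' @param t Time (h).
#' @param schedule List with `start` (h), `days`, `on_h`, `cycle_h`,
#'   `strength`.
#' @return Inhibition strength at `t` (0 when inactive).
#' @export
cdk1_schedule <- function(t, schedule) {
  if (is.null(schedule)) return(0)
  rel <- t - schedule$start
  if (rel < 0 || rel >= schedule$days * 24) return(0)
  if ((rel %% schedule$cycle_h) < schedule$on_h) schedule$strength else 0
}
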