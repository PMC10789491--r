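# Cell-cycle protein network ----------------------------------------------
#
# Each proliferative cell carries a reduced cyclin/CDK relay oscillator with
# seven species (A.U. concentrations):
#
#   CycE_t : total cyclin E-CDK2 pool (free activity e is obtained by
#            titration against the stoichiometric inhibitors p27 + p21)
#   CycA   : cyclin A-CDK1/2 activity
#   CycB   : cyclin B-CDK1 activity
#   Wee1   : Wee1 kinase (high in G1/S, inactivated by rising CycB-CDK1)
#   p27    : CDK inhibitor; production rate set by intercellular pressure
#   p21    : CDK inhibitor; production driven by DNA damage
#   Cdc20  : APC/C-Cdc20, activated by high CycB at mitosis; drives the
#            M-exit degradation surge of CycA then CycB
#   Cdh1   : APC/C-Cdh1 (0..1), active in G1 where it keeps CycA/CycB at
#            zero; inactivated by rising CDK activity at Start
#
# The relay realises the marker-event order used for phase annotation:
# free CycE rises (G1 -> S), Wee1 falls (S -> G2), CycA falls (G2 -> M),
# CycB falls (M -> division).  G1 duration is controlled almost entirely by
# the p27 production rate: CycE_t must titrate past the inhibitor pool
# before free CycE activity ignites, so G1 lengthens roughly linearly with
# p27 production while S/G2/M are unchanged.
#
# Pressure feeds p27 production through a saturating Hill function
# (contact inhibition of proliferation); DNA damage feeds p21; RNA damage
# scales all protein production globally; CDK1 inhibition scales the
# production of CycA and CycB only.

CYCLE_SPECIES <- c("CycE_t", "CycA", "CycB", "Wee1", "p27", "p21",
                   "Cdc20", "Cdh1")

PHASE_LEVELS <- c("G1", "S", "G2", "M")

#' Default cell-cycle network parameters
#'
#' Rate constants (per hour) and thresholds of the cyclin/CDK relay
#' oscillator.  The base parameterization gives a free-running period of
#' roughly 8.1 h at zero p27 production (transit-amplifying behaviour); the
#' pressure coupling (see [couple_pressure()]) raises the p27 production
#' rate up to `q_sat`, which lengthens G1 so that the saturated period is
#' about 21.5 h (niche behaviour).
#'
#' @return Named list of parameters.
#' @export
cycle_params <- function() {
  list(
    # CycE_t: basal + autocatalytic production, inhibited pool titration
    kse = 1.50, e0 = 0.12, KE = 0.30, kde = 0.10, kdea = 0.30, kdeb = 0.30,
    KBE = 0.50,
    Kd_inh = 0.02,            # tight-binding Kd of p27/p21 vs CycE
    # CycA (production driven by free CycE activity)
    ksa = 1.80, KEA = 0.50, kda = 0.10, kda20 = 5.00, kdah = 2.00,
    # CycB (production switched on by high CycA)
    ksb = 3.00, KAB = 2.00, nab = 4, kdb = 0.15, kdb20 = 3.00, kdbh = 1.50,
    # Wee1 (inactivated by rising CycB-CDK1)
    ksw = 1.00, kdw = 0.70, kdwa = 5.00, KBW = 0.80,
    # p27
    kdq = 0.25, kdqe = 1.00,
    # p21
    kdp = 0.10,
    # Cdc20 (M-exit surge)
    ks20 = 2.50, KBC = 2.60, nbc = 6, kd20 = 1.50,
    # Cdh1 (G1 keeper; inactivated by CDK activity)
    kah = 0.50, kih = 2.00, ca = 0.30, cb = 0.30,
    # global tempo: uniform time rescaling of the whole network
    tempo = 0.68,
    # phase-annotation thresholds (half-maximum crossings on the
    # unperturbed limit cycle; frozen numerics, see vignette)
    th_e = 0.30, th_w = 0.50, th_a = 1.80, th_b = 0.40,
    # pressure -> p27 production (Hill exponent 2, saturating)
    q_sat = 0.64, Kp = 0.95, P0 = 0.50,
    # mass growth: fast early-cycle growth braked logistically at
    # mass_cap x birth mass, so division mass is ~2x birth mass at the
    # expected period for the cell's p27 production rate
    period_T0 = 8.13, period_slope = 32.0, growth_boost = 3.6,
    mass_cap = 2.2,          # absolute division-mass target (A.U.)
    # CDK1-inhibition outcome logic
    kd_cdk1i = 0.10,         # inhibitor-induced complex destabilization (/h)
    mitotic_death_frac = 0.20,
    p_mitotic_death = 0.35,  # death probability among severity-eligible
                             # M-phase cells (the rest restart oversized)
    # damage coupling
    k_p21 = 0.27, th_p21 = 0.25,     # p21 production above DNA-damage floor
    k_rna_slow = 1.0,                # sigma = 1/(1 + k_rna_slow * rna)
    p21_arrest = 6.0, sigma_arrest = 0.45,
    giant_mass = 6.0, division_mass = 2.0
  )
}

#' Free CycE-CDK2 activity by inhibitor titration
#'
#' Tight-binding solution for the free concentration of a ligand (total
#' `et`) in the presence of a stoichiometric inhibitor pool (`inh`) with
#' dissociation constant `Kd`.
#'
#' @param et Total CycE pool (vector).
#' @param inh Inhibitor pool, p27 + p21 (vector).
#' @param Kd Dissociation constant.
#' @return Free activity, same length as `et`.
#' @keywords internal
free_cyce <- function(et, inh, Kd) {
  b <- et - inh - Kd
  0.5 * (b + sqrt(b * b + 4 * Kd * et))
}

# Derivatives of the network for a matrix of cells.
# S: n x 7 matrix (columns CYCLE_SPECIES); q, sigma, rho, p21_prod: length-n
# vectors (recycled if scalar).  Returns n x 7 matrix.
cycle_deriv <- function(S, pars, q, sigma = 1, rho = 1, p21_prod = 0) {
  et <- S[, 1L]; A <- S[, 2L]; B <- S[, 3L]; W <- S[, 4L]
  Q <- S[, 5L]; P <- S[, 6L]; C20 <- S[, 7L]; H <- S[, 8L]
  e <- free_cyce(et, Q + P, pars$Kd_inh)
  e2 <- e * e
  B6 <- (pmax(B, 0) / pars$KBC)^pars$nbc
  A4 <- (pmax(A, 0) / pars$KAB)^pars$nab
  A2 <- A * A
  cdk <- e2 + pars$ca * A2 + pars$cb * B * B

  dEt <- sigma * pars$kse * (pars$e0 + (1 - pars$e0) * e2 / (pars$KE^2 + e2)) /
    (1 + (B / pars$KBE)^2) -
    (pars$kde + pars$kdea * A + pars$kdeb * B) * et
  # CDK1 inhibition (rho < 1) suppresses CycA/CycB production and also
  # destabilizes the existing complexes (kinase-dead complexes are
  # degraded), which is what drives the early CycB fall behind the
  # premature-G1-restart and mitotic-death phenotypes
  kd_i <- pars$kd_cdk1i * (1 - rho)
  dA <- sigma * rho * pars$ksa * e2 / (pars$KEA^2 + e2) -
    (pars$kda + kd_i + pars$kda20 * C20 + pars$kdah * H) * A
  dB <- sigma * rho * pars$ksb * A4 / (1 + A4) -
    (pars$kdb + kd_i + pars$kdb20 * C20 + pars$kdbh * H) * B
  dW <- sigma * pars$ksw - pars$kdw * W -
    pars$kdwa * (B * B / (pars$KBW^2 + B * B)) * W
  dQ <- sigma * q - pars$kdq * Q - pars$kdqe * e2 * Q
  dP <- p21_prod - pars$kdp * P
  dC20 <- sigma * pars$ks20 * B6 / (1 + B6) - pars$kd20 * C20
  dH <- pars$kah * (1 - H) - pars$kih * cdk * H

  pars$tempo * cbind(dEt, dA, dB, dW, dQ, dP, dC20, dH,
                     deparse.level = 0L)
}

#' Initial cycle state for newly proliferative cells
#'
#' Cells start in the network's natural post-mitotic (early G1) state,
#' sampled from the settled limit cycle just after a division event, with
#' the p27 pool at half its production steady state (it is partially
#' rebuilt during the preceding S/G2/M).  With this start the first
#' birth-to-division interval matches the free-running period.
#'
#' @param n Number of cells.
#' @param q p27 production rate(s).
#' @param pars Cycle parameters.
#' @return `n x 8` matrix with columns `CYCLE_SPECIES`.
#' @export
cycle_state_init <- function(n, q = 0, pars = cycle_params()) {
  post <- c(CycE_t = 0.373, CycA = 0.436, CycB = 0.396, Wee1 = 0.442,
            p27 = 0, p21 = 0, Cdc20 = 0.0155, Cdh1 = 0.426)
  S <- matrix(rep(post, each = n), nrow = n,
              dimnames = list(NULL, CYCLE_SPECIES))
  S[, "p27"] <- 0.5 * rep_len(q, n) / pars$kdq
  S
}

# One RK4 step of the network for all cells (matrix in, matrix out).
cycle_rk4 <- function(S, h, pars, q, sigma, rho, p21_prod) {
  k1 <- cycle_deriv(S, pars, q, sigma, rho, p21_prod)
  k2 <- cycle_deriv(S + 0.5 * h * k1, pars, q, sigma, rho, p21_prod)
  k3 <- cycle_deriv(S + 0.5 * h * k2, pars, q, sigma, rho, p21_prod)
  k4 <- cycle_deriv(S + h * k3, pars, q, sigma, rho, p21_prod)
  out <- S + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  out[out < 0] <- 0
  out
}

#' Advance the cell-cycle network and annotate phase events
#'
#' Integrates the protein network for a population of cells over `dt`
#' (fixed-step RK4) and runs the ordered phase state machine on marker
#' crossings: free CycE up through `th_e` ends G1; Wee1 down through `th_w`
#' ends S; CycA down through `th_a` ends G2 (M entry); CycB down through
#' `th_b` ends M.  A CycB down-crossing in M is a division event, except
#' while CDK1 inhibition is active, when it becomes either a mitotic death
#' (CycB fell below `mitotic_death_frac` of its M-entry value while still
#' in M) or a division-less premature G1 restart.
#'
#' @param state List with elements `S` (n x 8 species matrix), `phase`
#'   (integer 1..4 = G1,S,G2,M), `mass` (numeric), `b_entry` (CycB value at
#'   M entry), `cycle_start` (hours).
#' @param dt Time step (hours), > 0 (0 returns the state unchanged).
#' @param perturbations List with optional per-cell vectors `q` (p27
#'   production), `sigma` (global production scaling from RNA damage),
#'   `rho` (CDK1-inhibition production scaling on CycA/CycB; 1 = none),
#'   `p21_prod` (p21 production from DNA damage), and scalar flag
#'   `cdk1_active`.
#' @param pars Cycle parameters.
#' @param t Absolute time at the start of the step (hours), used only to
#'   stamp `cycle_start` on division/restart.
#' @param substeps RK4 substeps within `dt`.
#' @return The updated `state`, plus logical event vectors `divided`,
#'   `mitotic_death`, `restarted`, `entered_s`, `entered_m`.
#' @export
integrate_cycle <- function(state, dt, perturbations = list(),
                            pars = cycle_params(), t = 0, substeps = 2L) {
  n <- nrow(state$S)
  divided <- logical(n); death <- logical(n); restarted <- logical(n)
  entered_s <- logical(n); entered_m <- logical(n)
  if (n == 0L || dt <= 0) {
    state$divided <- divided; state$mitotic_death <- death
    state$restarted <- restarted
    state$entered_s <- entered_s; state$entered_m <- entered_m
    return(state)
  }
  q <- rep_len(perturbations$q %||% 0, n)
  sigma <- rep_len(perturbations$sigma %||% 1, n)
  rho <- rep_len(perturbations$rho %||% 1, n)
  p21p <- rep_len(perturbations$p21_prod %||% 0, n)
  cdk1 <- isTRUE(perturbations$cdk1_active)
  # among severity-eligible M-phase cells, mitotic death strikes with
  # probability p_mitotic_death; the caller supplies the uniform draws
  # (the default 0 makes the severity criterion deterministic)
  p_death <- perturbations$p_death %||% pars$p_mitotic_death
  death_draws <- rep_len(perturbations$death_draws %||% 0, n)

  S <- state$S
  phase <- state$phase
  b_entry <- state$b_entry
  h <- dt / substeps
  # mass grows logistically towards an absolute target (the normal
  # division mass); the absolute anchor makes cell size self-correcting
  # across generations.  A division-less restart doubles the target
  # (replicated genome without cytokinesis), which is how oversized and
  # ultimately giant cells arise under CDK1 inhibition.
  mu <- pars$growth_boost * log(2) /
    (pars$period_T0 + pars$period_slope * q)
  mass_target <- state$mass_target %||% rep(pars$mass_cap, n)
  frozen <- state$frozen %||% logical(n)

  for (s in seq_len(substeps)) {
    e_prev <- free_cyce(S[, 1L], S[, 5L] + S[, 6L], pars$Kd_inh)
    S_new <- cycle_rk4(S, h, pars, q, sigma, rho, p21p)
    if (any(!is.finite(S_new))) {
      bad <- !stats::complete.cases(is.finite(S_new) * 1)
      bad <- rowSums(!is.finite(S_new)) > 0
      warning("cell-cycle integration produced non-finite state; ",
              sum(bad), " cell(s) frozen")
      S_new[bad, ] <- S[bad, ]
      frozen <- frozen | bad
    }
    if (any(frozen)) S_new[frozen, ] <- S[frozen, ]
    e_new <- free_cyce(S_new[, 1L], S_new[, 5L] + S_new[, 6L], pars$Kd_inh)

    live <- !frozen
    # ordered transitions; G1 -> S is level-triggered so that fast cells
    # with no inhibitor pool can shorten/omit G1
    g1s <- live & phase == 1L & e_new >= pars$th_e
    sg2 <- live & phase == 2L & S[, 4L] > pars$th_w & S_new[, 4L] <= pars$th_w
    g2m <- live & phase == 3L & S[, 2L] > pars$th_a & S_new[, 2L] <= pars$th_a
    mX  <- live & phase == 4L & S[, 3L] > pars$th_b & S_new[, 3L] <= pars$th_b

    phase[g1s] <- 2L
    entered_s <- entered_s | g1s
    phase[sg2] <- 3L
    if (any(g2m)) {
      phase[g2m] <- 4L
      b_entry[g2m] <- S_new[g2m, 3L]
      entered_m <- entered_m | g2m
    }
    if (any(mX)) {
      if (cdk1) {
        sev <- mX & (S_new[, 3L] <= pars$mitotic_death_frac * b_entry)
        die <- sev & death_draws < p_death
        death[die] <- TRUE
        res <- mX & !die
        restarted[res] <- TRUE
        phase[res] <- 1L
      } else {
        divided[mX] <- TRUE
        phase[mX] <- 1L
      }
    }
    # premature G1 restart from a collapsing G2 never reaches M-entry in
    # the usual way; the A down-crossing above routes it through a brief
    # "M" with low CycB, which resolves via the mX branch.
    S <- S_new
  }
  state$S <- S
  state$phase <- phase
  state$b_entry <- b_entry
  grow <- ifelse(frozen, 0, mu) * pmax(0, 1 - state$mass / mass_target)
  state$mass <- state$mass * exp(grow * dt)
  if (any(restarted)) mass_target[restarted] <- 2 * mass_target[restarted]
  state$mass_target <- mass_target
  state$frozen <- frozen
  state$divided <- divided
  state$mitotic_death <- death
  state$restarted <- restarted
  state$entered_s <- entered_s
  state$entered_m <- entered_m
  if (any(divided | restarted)) {
    state$cycle_start[divided | restarted] <- t + dt
  }
  state
}

#' Annotate the current phase from protein levels alone
#'
#' Stateless classification used for spot checks: G1 when free CycE is
#' below threshold and Wee1 high; S when CycE has risen but Wee1 is still
#' high; G2 when Wee1 has fallen and CycA is high; M when CycA has fallen
#' and CycB is still above its exit threshold.  The running simulation uses
#' the ordered crossing state machine in [integrate_cycle()]; this function
#' agrees with it on the unperturbed limit cycle.
#'
#' @param state List with `S` matrix (or a single named 7-vector).
#' @param pars Cycle parameters.
#' @return Character vector of phases.
#' @export
annotate_phase <- function(state, pars = cycle_params()) {
  S <- if (is.matrix(state$S %||% state)) (state$S %||% state) else
    matrix(state$S %||% state, nrow = 1,
           dimnames = list(NULL, CYCLE_SPECIES))
  e <- free_cyce(S[, 1L], S[, 5L] + S[, 6L], pars$Kd_inh)
  out <- rep("G1", nrow(S))
  out[e >= pars$th_e & S[, 4L] > pars$th_w] <- "S"
  out[S[, 4L] <= pars$th_w & S[, 2L] > pars$th_a] <- "G2"
  out[S[, 4L] <= pars$th_w & S[, 2L] <= pars$th_a & S[, 3L] > pars$th_b] <- "M"
  out
}

#' Map intercellular pressure to p27 production rate
#'
#' Saturating Hill function (exponent 2) of the pressure in excess of an
#' activation threshold `P0`, realizing contact inhibition of
#' proliferation: pressures at or below `P0` (the transit-amplifying
#' regime) give the minimal (zero) p27 production and the shortest cycle;
#' pressures in the niche range drive production towards `q_sat`, giving
#' ~21.5 h cycles.  The threshold reflects that low contact forces do not
#' engage the mechanosensing pathway.
#'
#' @param pressure Non-negative pressure reading(s) (A.U.).
#' @param pars Cycle parameters (`q_sat`, `Kp`).
#' @return p27 production rate(s) (A.U./h).
#' @export
couple_pressure <- function(pressure, pars = cycle_params()) {
  p2 <- pmax(pressure - pars$P0, 0)^2
  pars$q_sat * p2 / (pars$Kp^2 + p2)
}

#' CDK1-inhibition perturbation
#'
#' Returns the production scaling applied to CycA and CycB while a CDK1
#' inhibitor is active: `rho = max(0, 1 - strength)`.  Outcome
#' classification (unaffected / premature G1 restart with oversized cells /
#' mitotic death) is performed inside [integrate_cycle()] via the
#' `cdk1_active` flag.
#'
#' @param strength Inhibition strength in `[0, 1]`; values near 1 suppress
#'   production almost completely.
#' @param active Logical; inactive returns 1 (no perturbation).
#' @return Production scale factor.
#' @export
apply_cdk1_inhibition <- function(strength, active = TRUE) {
  stopifnot(strength >= 0)
  if (!active) return(1)
  max(0, 1 - strength)
}

#' Damage coupling of the cycle
#'
#' DNA damage above a floor drives p21 production (G1/S brake through the
#' same titration pool as p27); RNA damage scales global protein production
#' down by `sigma = 1/(1 + k_rna_slow * rna)`.  The combined slowdown
#' arrests the cycle outright (no further phase transitions) when p21
#' exceeds `p21_arrest` or `sigma` falls below `sigma_arrest`.
#'
#' @param dna_damage,rna_damage Non-negative damage levels (A.U.).
#' @param pars Cycle parameters.
#' @return List with `p21_prod`, `sigma`, and logical `arrest`.
#' @export
apply_damage_coupling <- function(dna_damage, rna_damage,
                                  pars = cycle_params()) {
  stopifnot(all(dna_damage >= 0), all(rna_damage >= 0))
  p21_prod <- pars$k_p21 * pmax(0, dna_damage - pars$th_p21)
  sigma <- 1 / (1 + pars$k_rna_slow * rna_damage)
  list(p21_prod = p21_prod, sigma = sigma,
       arrest = sigma < pars$sigma_arrest)
}

#' Free-running cycle period at a given p27 production rate
#'
#' Integrates a single unperturbed cell and reports the mean interval
#' between successive division events (after discarding the first cycle).
#'
#' @param q p27 production rate (scalar or vector; cells are integrated
#'   together, one per rate).
#' @param pars Cycle parameters.
#' @param t_max Simulated hours.
#' @param dt Step (hours).
#' @return Numeric vector of periods (hours); `NA` when fewer than two
#'   divisions occurred.
#' @export
cycle_period <- function(q, pars = cycle_params(), t_max = 130, dt = 0.02) {
  n <- length(q)
  st <- list(S = cycle_state_init(n, q, pars), phase = rep(1L, n),
             mass = rep(1, n), b_entry = rep(1, n),
             cycle_start = rep(0, n))
  div_times <- vector("list", n)
  t <- 0
  while (t < t_max) {
    st <- integrate_cycle(st, dt, list(q = q), pars, t = t, substeps = 1L)
    if (any(st$divided)) {
      for (i in which(st$divided)) {
        div_times[[i]] <- c(div_times[[i]], t + dt)
        st$mass[i] <- st$mass[i] / 2
      }
    }
    t <- t + dt
  }
  vapply(div_times, function(d) {
    if (length(d) < 3L) return(NA_real_)
    mean(diff(d[-1L]))
  }, numeric(1))
}

#' Phase durations on the limit cycle
#'
#' Integrates one unperturbed cell, records the marker-crossing times, and
#' returns the mean duration of each phase on the settled limit cycle.
#'
#' @inheritParams cycle_period
#' @return Named numeric vector (hours) for G1, S, G2, M.
#' @export
cycle_phase_durations <- function(q = 0, pars = cycle_params(),
                                  t_max = 130, dt = 0.02) {
  st <- list(S = cycle_state_init(1L, q, pars), phase = 1L,
             mass = 1, b_entry = 1, cycle_start = 0)
  rec <- list(time = numeric(0), phase = integer(0))
  t <- 0
  prev_phase <- 1L
  changes <- data.frame(time = numeric(0), from = integer(0),
                        to = integer(0))
  while (t < t_max) {
    st <- integrate_cycle(st, dt, list(q = q), pars, t = t, substeps = 1L)
    if (st$divided) st$mass <- st$mass / 2
    if (st$phase != prev_phase || st$divided) {
      changes <- rbind(changes,
                       data.frame(time = t + dt, from = prev_phase,
                                  to = st$phase))
      prev_phase <- st$phase
    }
    t <- t + dt
  }
  if (nrow(changes) < 9L) {
    return(c(G1 = NA_real_, S = NA_real_, G2 = NA_real_, M = NA_real_))
  }
  # keep settled cycles: drop the first full cycle
  g1_starts <- changes$time[changes$to == 1L]
  if (length(g1_starts) < 3L) {
    return(c(G1 = NA_real_, S = NA_real_, G2 = NA_real_, M = NA_real_))
  }
  window <- changes[changes$time >= g1_starts[1L] &
                      changes$time <= g1_starts[length(g1_starts)], ]
  durs <- c(G1 = 0, S = 0, G2 = 0, M = 0)
  counts <- c(0, 0, 0, 0)
  for (i in seq_len(nrow(window) - 1L)) {
    ph <- window$to[i]
    durs[ph] <- durs[ph] + (window$time[i + 1L] - window$time[i])
    counts[ph] <- counts[ph] + 1L
  }
  durs / pmax(counts, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
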