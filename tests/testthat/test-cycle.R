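# Cell-cycle protein network

test_that("unperturbed network oscillates through all four phases in order", {
  pars <- cycle_params()
  st <- list(S = cycle_state_init(1, 0, pars), phase = 1L, mass = 1,
             b_entry = NA_real_, cycle_start = 0)
  phases <- integer(0)
  t <- 0
  while (t < 30) {
    st <- integrate_cycle(st, 0.02, list(q = 0), pars, t = t, substeps = 1L)
    if (st$divided) st$mass <- st$mass / 2
    phases <- c(phases, st$phase)
    t <- t + 0.02
  }
  expect_setequal(unique(phases), 1:4)
  # transitions only in cyclic order G1->S->G2->M->G1
  tr <- unique(cbind(phases[-length(phases)], phases[-1]))
  tr <- tr[tr[, 1] != tr[, 2], , drop = FALSE]
  valid <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  expect_true(all(apply(tr, 1, function(x)
    any(x[1] == valid[, 1] & x[2] == valid[, 2]))))
})

test_that("zero dt leaves the state unchanged", {
  pars <- cycle_params()
  st <- list(S = cycle_state_init(2, c(0, 0.2), pars), phase = c(1L, 1L),
             mass = c(1, 1), b_entry = rep(NA_real_, 2), cycle_start = c(0, 0))
  out <- integrate_cycle(st, 0, list(q = c(0, 0.2)), pars)
  expect_identical(out$S, st$S)
  expect_false(any(out$divided))
})

test_that("p27 production lengthens the period monotonically (10-rate sweep)", {
  qs <- seq(0, 0.36, length.out = 10)
  per <- cycle_period(qs, t_max = 100)
  expect_false(anyNA(per))
  expect_true(all(diff(per) >= -0.05))   # non-decreasing up to grid noise
  expect_gt(per[10], per[1] * 1.8)
})

test_that("the p27 effect is G1-targeted", {
  d_lo <- cycle_phase_durations(0.02)
  d_hi <- cycle_phase_durations(0.30)
  dG1 <- d_hi["G1"] - d_lo["G1"]
  dT <- sum(d_hi) - sum(d_lo)
  expect_gt(dG1 / dT, 0.6)
  # S-phase duration much less variable than G1
  expect_lt(abs(d_hi["S"] - d_lo["S"]), 0.3 * dG1)
})

test_that("phase durations partition the oscillation period", {
  q <- 0.1
  durs <- cycle_phase_durations(q)
  per <- cycle_period(q)
  expect_equal(sum(durs), per, tolerance = 0.05)
})

test_that("trajectories from perturbed starts converge to one period", {
  pars <- cycle_params()
  set.seed(42)
  periods <- sapply(1:5, function(i) {
    st <- list(S = cycle_state_init(1, 0.1, pars) *
                 matrix(runif(8, 0.5, 1.5), 1), phase = 1L, mass = 1,
               b_entry = NA_real_, cycle_start = 0)
    divs <- numeric(0); t <- 0
    while (t < 80) {
      st <- integrate_cycle(st, 0.02, list(q = 0.1), pars, t = t,
                            substeps = 1L)
      if (st$divided) { st$mass <- st$mass / 2; divs <- c(divs, t) }
      t <- t + 0.02
    }
    # period after at most 3 cycles of transient
    mean(diff(divs[-(1:3)]))
  })
  expect_lt(max(periods) - min(periods), 0.15)
})

test_that("pressure coupling is a saturating Hill map with calibrated anchors", {
  pars <- cycle_params()
  expect_equal(couple_pressure(0, pars), 0)
  ps <- seq(0, 10, length.out = 10)
  qs <- couple_pressure(ps, pars)
  expect_true(all(diff(qs) > 0))
  expect_lt(max(qs), pars$q_sat)
  # periods inherit the monotonicity
  per <- cycle_period(couple_pressure(c(0.2, 1, 3), pars))
  expect_true(all(diff(per) > 0))
})

test_that("CDK1 inhibition outcome depends on cycle position", {
  pars <- cycle_params()
  run_pulse <- function(offset_frac, q = 0.25, draws = 0) {
    st <- list(S = cycle_state_init(1, q, pars), phase = 1L, mass = 1,
               b_entry = NA_real_, cycle_start = 0)
    divs <- numeric(0); t <- 0
    while (length(divs) < 2 && t < 60) {
      st <- integrate_cycle(st, 0.02, list(q = q), pars, t = t,
                            substeps = 1L)
      if (st$divided) { st$mass <- st$mass / 2; divs <- c(divs, t) }
      t <- t + 0.02
    }
    period <- diff(divs)[1]
    pulse_start <- divs[2] + offset_frac * period
    out <- list(died = FALSE, restarted = FALSE, next_div = NA, mass = NA)
    while (t < pulse_start + 40) {
      on <- t >= pulse_start && t < pulse_start + 6
      st <- integrate_cycle(st, 0.02,
                            list(q = q, rho = if (on) 0.05 else 1,
                                 cdk1_active = on, death_draws = draws),
                            pars, t = t, substeps = 1L)
      if (st$mitotic_death) { out$died <- TRUE; break }
      if (st$restarted) out$restarted <- TRUE
      if (st$divided) {
        st$mass <- st$mass / 2
        if (is.na(out$next_div)) out$next_div <- t
      }
      t <- t + 0.02
    }
    out$period <- period
    out$pulse_start <- pulse_start
    out$mass <- st$mass
    out
  }
  # early G1 (long-G1 regime): unaffected, next division barely shifted
  early <- run_pulse(0.05)
  expect_false(early$died || early$restarted)
  expect_lt(abs((early$next_div - early$pulse_start) -
                  (1 - 0.05) * early$period), 0.1 * early$period)
  # late G2: stalls at the boundary (CycB-CDK1 is required for M entry),
  # resumes after the pulse and divides late, without dying
  late_g2 <- run_pulse(0.76)
  expect_false(late_g2$died)
  expect_gt(late_g2$next_div - late_g2$pulse_start,
            0.3 * late_g2$period)
  # mid-M, severe cyclin collapse: mitotic death (deterministic draw 0)
  m_cell <- run_pulse(0.88)
  expect_true(m_cell$died)
  # the same M-phase cell escaping the death lottery fails cytokinesis
  # and restarts G1 instead
  m_surv <- run_pulse(0.88, draws = 1)
  expect_false(m_surv$died)
  expect_true(m_surv$restarted)
})

test_that("a division-less restart roughly doubles end-of-cycle mass", {
  pars <- cycle_params()
  q <- 0.25
  st <- list(S = cycle_state_init(1, q, pars), phase = 1L, mass = 1,
             b_entry = NA_real_, cycle_start = 0)
  divs <- numeric(0); t <- 0
  mass_at_div <- NA
  while (length(divs) < 2 && t < 60) {
    st <- integrate_cycle(st, 0.02, list(q = q), pars, t = t, substeps = 1L)
    if (st$divided) { mass_at_div <- st$mass; st$mass <- st$mass / 2
      divs <- c(divs, t) }
    t <- t + 0.02
  }
  period <- diff(divs)[1]
  pulse_start <- divs[2] + 0.88 * period
  restarted <- FALSE
  while (t < pulse_start + 60) {
    on <- t >= pulse_start && t < pulse_start + 6
    st <- integrate_cycle(st, 0.02, list(q = q, rho = if (on) 0.05 else 1,
                                         cdk1_active = on,
                                         death_draws = 1), pars, t = t,
                          substeps = 1L)
    if (st$restarted) restarted <- TRUE
    if (st$divided) break
    t <- t + 0.02
  }
  expect_true(restarted)
  # end-of-(division-less)-cycle mass approaches twice the normal
  # end-of-cycle mass
  expect_gt(st$mass, 0.75 * 2 * mass_at_div)
})

test_that("damage coupling slows and ultimately arrests the cycle", {
  pars <- cycle_params()
  # no damage -> dynamics identical to unperturbed
  d0 <- apply_damage_coupling(0, 0, pars)
  expect_equal(d0$p21_prod, 0)
  expect_equal(d0$sigma, 1)
  expect_false(d0$arrest)
  per_with <- function(p21p, sigma) {
    st <- list(S = cycle_state_init(1, 0, pars), phase = 1L, mass = 1,
               b_entry = NA_real_, cycle_start = 0)
    divs <- numeric(0); t <- 0
    while (t < 90) {
      st <- integrate_cycle(st, 0.02, list(q = 0, sigma = sigma,
                                           p21_prod = p21p), pars, t = t,
                            substeps = 1L)
      if (st$divided) { st$mass <- st$mass / 2; divs <- c(divs, t) }
      t <- t + 0.02
    }
    if (length(divs) < 3) NA else mean(diff(divs[-1]))
  }
  base <- per_with(0, 1)
  # DNA damage just above the p21 floor -> strictly longer period
  dmg <- apply_damage_coupling(cycle_params()$th_p21 + 0.05, 0, pars)
  slowed <- per_with(dmg$p21_prod, dmg$sigma)
  expect_gt(slowed, base + 0.3)
  # arrest-level combined damage -> no further divisions
  heavy <- apply_damage_coupling(3, 2, pars)
  expect_true(heavy$arrest)
  expect_true(is.na(per_with(heavy$p21_prod, heavy$sigma)))
})

test_that("phase annotation matches marker logic on the limit cycle", {
  pars <- cycle_params()
  st <- list(S = cycle_state_init(1, 0.15, pars), phase = 1L, mass = 1,
             b_entry = NA_real_, cycle_start = 0)
  t <- 0
  agree <- 0L; total <- 0L
  while (t < 60) {
    st <- integrate_cycle(st, 0.02, list(q = 0.15), pars, t = t,
                          substeps = 1L)
    if (st$divided) st$mass <- st$mass / 2
    if (t > 20) {
      total <- total + 1L
      if (annotate_phase(st, pars) == PHASE_LEVELS[st$phase]) {
        agree <- agree + 1L
      }
    }
    t <- t + 0.02
  }
  expect_gt(agree / total, 0.9)
})

test_that("high Wee1 with low cyclins annotates as G1", {
  pars <- cycle_params()
  S <- cycle_state_init(1, 0, pars)
  S[1, "Wee1"] <- 1.4; S[1, c("CycE_t", "CycA", "CycB")] <- 0.01
  expect_equal(annotate_phase(list(S = S), pars), "G1")
})
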