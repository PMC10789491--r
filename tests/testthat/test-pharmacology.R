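# 5-FU PK, damage accumulation, checkpoints, CDK1 schedule

test_that("no doses means zero concentrations forever", {
  tr <- pk_trace(NULL, t_max = 24)
  expect_true(all(tr[, c("fu", "futp", "fdump", "fdutp")] == 0))
})

test_that("the PK system is exactly linear in dose", {
  sched1 <- data.frame(time = c(1, 13), dose = c(50, 50))
  sched2 <- data.frame(time = c(1, 13), dose = c(100, 100))
  t1 <- pk_trace(sched1, t_max = 24)
  t2 <- pk_trace(sched2, t_max = 24)
  for (sp in c("fu", "futp", "fdutp")) {
    expect_equal(t2[[sp]], 2 * t1[[sp]], tolerance = 1e-10)
  }
})

test_that("q12h dosing gives repeated peaks with near-complete washout", {
  sched <- data.frame(time = seq(0, by = 12, length.out = 8), dose = 50)
  tr <- pk_trace(sched, t_max = 96, dt = 0.05)
  # peak shortly after each dose, trough just before the next
  for (k in 1:3) {
    seg <- tr[tr$time > (k - 1) * 12 & tr$time < k * 12 - 0.1, ]
    expect_gt(max(seg$fu), 100 * seg$fu[nrow(seg)])     # washout of parent
    expect_gt(max(seg$futp), 5 * seg$futp[nrow(seg)])   # metabolite decays
  }
  expect_error(integrate_pk(pk_init(), data.frame(time = 1, dose = -5),
                            0.1, 0, default_config()$pharmacology),
               "negative dose")
})

test_that("damage accrues by phase and cell state, and repairs on washout", {
  w <- make_fixture("checkerboard_niche")
  ph <- w$config$pharmacology
  w$pk["futp"] <- 1000; w$pk["fdutp"] <- 1000
  # force one proliferative cell into S, another into G1, one enterocyte
  s_cell <- which(w$cells$cycling)[1]
  g1_cell <- which(w$cells$cycling)[2]
  w$cycle$phase[s_cell] <- 2L
  w$cycle$phase[g1_cell] <- 1L
  ent <- which(!w$cells$cycling)[1]
  w2 <- accumulate_damage(w, dt = 1)
  expect_gt(w2$cells$rna[s_cell], 0)
  expect_gt(w2$cells$dna[s_cell], 0)
  expect_gt(w2$cells$rna[g1_cell], 0)
  expect_equal(w2$cells$dna[g1_cell], 0)     # FdUTP only during S-phase
  expect_equal(w2$cells$rna[ent], 0)         # non-proliferative: nothing
  expect_equal(w2$cells$dna[ent], 0)
  # washout: repair decays damage exponentially towards zero
  w2$pk[] <- 0
  d0 <- w2$cells$dna[s_cell]
  w3 <- accumulate_damage(w2, dt = 2)
  expect_equal(w3$cells$dna[s_cell], d0 * (1 - ph$repair_dna * 2),
               tolerance = 0.01)
})

test_that("checkpoint decisions follow the damage thresholds", {
  ph <- default_config()$pharmacology
  cp <- cycle_params()
  expect_equal(checkpoint_decision(0, 0, ph, cp), "CONTINUE")
  expect_equal(checkpoint_decision(cp$th_p21 + 0.1, 0, ph, cp), "SLOW")
  expect_equal(checkpoint_decision(ph$th_apopt_dna, 0, ph, cp), "APOPTOSIS")
  expect_equal(checkpoint_decision(0, ph$th_apopt_rna + 1, ph, cp),
               "APOPTOSIS")
})

test_that("CDK1 schedule is on for 6 h of every 12 h for four days", {
  sch <- list(start = 0, days = 4, on_h = 6, cycle_h = 12, strength = 0.95)
  expect_equal(cdk1_schedule(3, sch), 0.95)    # 3 h into day 1: active
  expect_equal(cdk1_schedule(9, sch), 0)       # 9 h into day 1: off
  expect_equal(cdk1_schedule(12 + 3, sch), 0.95)
  expect_equal(cdk1_schedule(4 * 24 + 1, sch), 0)   # day 5: treatment over
  expect_equal(cdk1_schedule(1, NULL), 0)
})

test_that("S-entry timing under 5-FU decides death at G2/M vs cycle completion", {
  # single-cell rehearsal of the high-dose challenge: a cell that enters
  # S at drug onset accumulates threshold DNA damage and dies at the G2/M
  # checkpoint; a cell at the end of S survives and finishes the cycle.
  cfg <- default_config()
  ph <- cfg$pharmacology
  pars <- cfg$cycle
  sched <- data.frame(time = 0, dose = 50)
  s_dur <- cycle_phase_durations(0, pars)[["S"]]
  run_cell <- function(phase_at_onset) {
    st <- list(S = cycle_state_init(1, 0, pars), phase = 1L, mass = 1,
               b_entry = NA_real_, cycle_start = 0)
    # advance drug-free until the cell reaches the requested phase point
    t <- 0
    t_s_entry <- NA
    while (t < 40) {
      st <- integrate_cycle(st, 0.02, list(q = 0), pars, t = t,
                            substeps = 1L)
      if (st$divided) st$mass <- st$mass / 2
      if (st$entered_s) t_s_entry <- t
      if (phase_at_onset == "S_start" && st$entered_s) break
      # "end of S": about three quarters of S already completed
      if (phase_at_onset == "S_end" && !is.na(t_s_entry) &&
          t - t_s_entry >= 0.75 * s_dur) break
      t <- t + 0.02
    }
    # drug applied from this moment; track damage and checkpoints
    pk <- pk_init()
    dna <- 0; rna <- 0
    died <- FALSE; completed <- FALSE
    t_drug <- 0
    while (t_drug < 30) {
      pk <- integrate_pk(pk, sched, 0.02, t_drug, ph)
      in_s <- st$phase == 2L
      dna <- max(0, dna + ph$k_dna * pk[["fdutp"]] * in_s * 0.02 -
                   ph$repair_dna * dna * 0.02)
      rna <- max(0, rna + ph$k_rna * pk[["futp"]] * 0.02 -
                   ph$repair_rna * rna * 0.02)
      dmg <- apply_damage_coupling(dna, rna, pars)
      st <- integrate_cycle(st, 0.02, list(q = 0, sigma = dmg$sigma,
                                           p21_prod = dmg$p21_prod),
                            pars, t = t_drug, substeps = 1L)
      if (st$entered_m &&
          checkpoint_decision(dna, rna, ph, pars) == "APOPTOSIS") {
        died <- TRUE; break
      }
      if (st$divided) { completed <- TRUE; break }
      t_drug <- t_drug + 0.02
    }
    list(died = died, completed = completed, dna = dna)
  }
  early <- run_cell("S_start")
  expect_true(early$died)
  late <- run_cell("S_end")
  expect_false(late$died)
  expect_true(late$completed)
  expect_lt(late$dna, ph$th_apopt_dna)
})
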