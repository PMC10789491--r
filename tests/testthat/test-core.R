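# Core state: configuration, determinism, conservation, step orchestration

test_that("configuration round-trips through YAML identically", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  unlink(f)
})

test_that("invalid configurations are rejected", {
  cfg <- default_config()
  cfg$geometry$radius <- -1
  expect_error(validate_config(cfg), "geometry")
  cfg <- default_config()
  cfg$run$dt <- 0
  expect_error(validate_config(cfg), "dt")
  cfg <- default_config()
  cfg$fate$wnt_high <- cfg$fate$wnt_low
  expect_error(validate_config(cfg), "wnt_high")
})

test_that("initialization is bit-identical under a fixed seed", {
  cfg <- mini_config(seed = 11)
  w1 <- initialize_world(cfg)
  w2 <- initialize_world(cfg)
  expect_identical(w1$cells, w2$cells)
  expect_identical(w1$cycle, w2$cycle)
  expect_identical(w1$villus, w2$villus)
})

test_that("the niche starts with intermingled stem and Paneth cells", {
  w <- initialize_world(default_config())
  niche <- w$cells$z <= 0
  expect_gt(sum(w$cells$type == CT_STEM & niche), 5)
  expect_gt(sum(w$cells$type == CT_PANETH & niche), 5)
  # intermingled: most stem cells touch at least one Paneth cell
  m <- secretory_neighbour_count(w)
  stems <- which(w$cells$type == CT_STEM & niche)
  expect_gt(mean(m[stems] >= 1), 0.7)
})

test_that("identical seeds give identical event logs over a short run", {
  cfg <- mini_config(seed = 4)
  w1 <- run_world(initialize_world(cfg), 6)
  w2 <- run_world(initialize_world(cfg), 6)
  expect_identical(event_log(w1), event_log(w2))
})

test_that("cell removals are conserved and logged with a cause", {
  cfg <- mini_config(seed = 9)
  w <- run_world(initialize_world(cfg), 24)
  ev <- event_log(w)
  births <- sum(ev$event == "birth")
  removal_events <- c("apoptosis", "mitotic_death", "ablation",
                      "villus_transfer", "shedding")
  removals <- sum(ev$event %in% removal_events & !is.na(ev$cell_id))
  # a division retires the mother and logs two births, so
  # births - removals - divisions = final count
  divisions <- sum(ev$event == "division")
  expect_equal(length(w$cells$id), births - removals - divisions)
  # mothers retire at division: division events pair with two births
  divs <- sum(ev$event == "division")
  expect_equal(sum(ev$event == "birth" & ev$time > 0), 2 * divs)
  # event log timestamps are non-decreasing
  expect_true(all(diff(ev$time) >= 0))
})

test_that("empty drug schedule leaves PK at zero; no cycling means no divisions", {
  w <- make_fixture("conveyor_villus")   # enterocytes only
  w <- step(w, 0.05)
  expect_true(all(w$pk == 0))
  w2 <- make_fixture("staining_columns")
  w2$cells$cycling[] <- FALSE
  w2 <- run_world(w2, 2)
  expect_equal(sum(event_log(w2)$event == "division"), 0)
})

test_that("cell ids are unique and never reused", {
  cfg <- mini_config(seed = 2)
  w <- run_world(initialize_world(cfg), 24)
  expect_false(any(duplicated(w$cells$id)))
  ev <- event_log(w)
  born <- ev$cell_id[ev$event == "birth"]
  expect_false(any(duplicated(born)))
})

test_that("cell-count trajectories are robust to the step size", {
  cfg <- mini_config(seed = 6)
  w1 <- run_world(initialize_world(cfg), 24, dt = 0.05)
  w2 <- run_world(initialize_world(cfg), 24, dt = 0.025)
  n1 <- length(w1$cells$id); n2 <- length(w2$cells$id)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.25)   # stochastic tolerance
})

test_that("scenario runner validates names and writes a replayable manifest", {
  expect_error(run_scenario("nonsense"), "unknown scenario")
  out <- tempfile()
  run <- run_scenario("homeostasis", seed = 3, days = 0.25,
                      config = mini_config(3), burn_in_days = 0.25,
                      out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_true(file.exists(file.path(out, "counts.csv")))
  man <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_equal(man$seed, 3)
  expect_equal(man$scenario, "homeostasis")
  unlink(out, recursive = TRUE)
})

test_that("fixtures validate basic world invariants on construction", {
  for (nm in list_fixtures()) {
    w <- make_fixture(nm, seed = 1)
    expect_false(any(duplicated(w$cells$id)), info = nm)
    expect_true(all(w$cells$wnt >= 0), info = nm)
    expect_true(all(w$cells$notch >= 0), info = nm)
    expect_true(all(w$cells$brdu >= 0 & w$cells$brdu <= 1), info = nm)
    if (length(w$cells$id)) {
      res <- surface_residual(cbind(w$cells$x, w$cells$y, w$cells$z),
                              w$config$geometry)
      expect_lt(max(res), 1e-6)
    }
  }
  expect_error(make_fixture("no_such"), "unknown fixture")
})
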