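# Fate rules, dedifferentiation, ablation

test_that("quadrant rules are mutually exclusive and exhaustive", {
  fate <- default_config()$fate
  grid <- expand.grid(wnt = seq(0, 20, length.out = 9),
                      notch = seq(0, 3, length.out = 9))
  for (i in seq_len(nrow(grid))) {
    tgt <- fate_target(CT_STEM, grid$wnt[i], grid$notch[i], bmp = 0,
                       divisions = 0, fate)
    expect_true(tgt %in% c(CT_STEM, CT_PANETH, CT_ABSORPTIVE_PROGENITOR,
                           CT_SECRETORY_PROGENITOR))
    # rules reproduce the quadrant structure (the Paneth fate requires
    # deep-niche Wnt, paneth_wnt_factor above the stemness threshold)
    expected <- if (grid$wnt[i] >= fate$wnt_high &&
                    grid$notch[i] >= fate$notch_on) {
      CT_STEM
    } else if (grid$wnt[i] >= fate$paneth_wnt_factor * fate$wnt_high &&
               grid$notch[i] < fate$notch_on) {
      CT_PANETH
    } else if (grid$notch[i] >= fate$notch_on) {
      CT_ABSORPTIVE_PROGENITOR
    } else {
      CT_SECRETORY_PROGENITOR
    }
    expect_identical(tgt, expected)
  }
})

test_that("absorptive progenitors differentiate in the 3-5 division band", {
  fate <- default_config()$fate
  hi_bmp <- 100
  # below min divisions: BMP cannot differentiate
  expect_identical(
    fate_target(CT_ABSORPTIVE_PROGENITOR, 2, 1, hi_bmp, 2, fate),
    CT_ABSORPTIVE_PROGENITOR)
  # 4 divisions with the BMP condition met -> enterocyte
  expect_identical(
    fate_target(CT_ABSORPTIVE_PROGENITOR, 2, 1, hi_bmp, 4, fate),
    CT_ENTEROCYTE)
  # 4 divisions, BMP below the trade-off line -> keeps cycling
  expect_identical(
    fate_target(CT_ABSORPTIVE_PROGENITOR, 2, 1, 0.1, 4, fate),
    CT_ABSORPTIVE_PROGENITOR)
  # forced at the top of the band while BMP is present
  expect_identical(
    fate_target(CT_ABSORPTIVE_PROGENITOR, 2, 1, 0.6, 5, fate),
    CT_ENTEROCYTE)
  # with the BMP relay collapsed (epithelial damage) progenitors keep
  # dividing past the band
  expect_identical(
    fate_target(CT_ABSORPTIVE_PROGENITOR, 2, 1, 0.1, 5, fate),
    CT_ABSORPTIVE_PROGENITOR)
})

test_that("dedifferentiation reverts the plastic set and only it", {
  fate <- default_config()$fate
  # reprogramming requires well-above-maintenance Wnt (hysteresis)
  hi <- fate$dediff_wnt_factor * fate$wnt_high + 1
  on <- fate$notch_on + 0.5
  expect_identical(dedifferentiate(CT_PANETH, hi, on, fate), CT_STEM)
  expect_identical(dedifferentiate(CT_ABSORPTIVE_PROGENITOR, hi, on, fate),
                   CT_STEM)
  expect_identical(dedifferentiate(CT_SECRETORY_PROGENITOR, hi, on, fate),
                   CT_STEM)
  # enterocytes are outside the plastic set at any signal level
  expect_identical(dedifferentiate(CT_ENTEROCYTE, hi, on, fate),
                   CT_ENTEROCYTE)
  # below either threshold: unchanged; maintenance-level Wnt alone does
  # not reprogram
  expect_identical(dedifferentiate(CT_PANETH, hi, 0, fate), CT_PANETH)
  expect_identical(dedifferentiate(CT_PANETH, 0, on, fate), CT_PANETH)
  expect_identical(
    dedifferentiate(CT_PANETH, fate$wnt_high + 1, on, fate), CT_PANETH)
})

test_that("committed fate switches are logged and dediff carries its origin", {
  w <- make_fixture("checkerboard_niche")
  k <- which(w$cells$type == CT_PANETH)[1]
  w$cells$wnt[k] <- w$config$fate$dediff_wnt_factor *
    w$config$fate$wnt_high * 2
  w$cells$notch[k] <- w$config$fate$notch_on * 2
  w$cells$pending_type[k] <- CT_STEM
  w$cells$pending_since[k] <- -100    # dwell satisfied
  w2 <- decide_fate(w)
  ev <- event_log(w2)
  dd <- ev[ev$event == "dedifferentiation", ]
  expect_gte(nrow(dd), 1)
  expect_true("PANETH" %in% dd$cell_type)
  expect_identical(w2$cells$type[k], CT_STEM)
})

test_that("stem ablation empties the stem pool and only acts in its window", {
  w <- make_fixture("checkerboard_niche")
  w$schedule$ablation <- list(start = 0, days = 4, lag = 1)
  w$cells$type_since[] <- -5          # all stems held long enough
  w2 <- ablate_stem(w, w$schedule$ablation)
  stems_marked <- w2$cells$apoptotic[w2$cells$type == CT_STEM]
  expect_true(all(stems_marked))
  expect_true(all(w2$cells$death_cause[w2$cells$apoptotic] == "ablation"))
  # outside the window: nothing happens
  w3 <- make_fixture("checkerboard_niche")
  w3$cells$type_since[] <- -5
  w3$time <- 4 * 24 + 10
  w3 <- ablate_stem(w3, list(start = 0, days = 4, lag = 1))
  expect_false(any(w3$cells$apoptotic))
})
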