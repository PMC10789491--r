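# Geometry and off-lattice mechanics

test_that("surface projection is idempotent and residual-free", {
  geom <- default_config()$geometry
  set.seed(7)
  pts <- cbind(runif(50, -3, 3), runif(50, -3, 3), runif(50, -3, 16))
  p1 <- surface_project(pts, geom)
  p2 <- surface_project(p1, geom)
  expect_lt(max(abs(p1 - p2)), 1e-9)
  expect_lt(max(surface_residual(p1, geom)), 1e-9)
})

test_that("longitudinal coordinates are continuous across the cap junction", {
  geom <- default_config()$geometry
  R <- geom$radius
  below <- surface_coords(matrix(c(R * sin(pi / 2 - 1e-4), 0,
                                   -R * cos(pi / 2 - 1e-4)), 1), geom)
  above <- surface_coords(matrix(c(R, 0, 1e-4), 1), geom)
  expect_lt(abs(below$s - above$s), 1e-3)
  expect_lt(abs(below$theta - above$theta), 1e-3)
})

test_that("neighbour detection matches an all-pairs brute-force oracle", {
  w <- make_fixture("mini_crypt", seed = 3)
  cf <- w$config$mechanics$contact_factor
  n <- length(w$cells$id)
  xyz <- cbind(w$cells$x, w$cells$y, w$cells$z)
  for (k in sample(n, 5)) {
    oracle <- integer(0)
    for (j in seq_len(n)) {
      if (j == k) next            # a cell is not its own neighbour
      d <- sqrt(sum((xyz[k, ] - xyz[j, ])^2))
      if (d < cf * (w$cells$radius[k] + w$cells$radius[j])) {
        oracle <- c(oracle, w$cells$id[j])
      }
    }
    expect_setequal(neighbours(w, w$cells$id[k]), oracle)
  }
})

test_that("distant cells are not neighbours and the relation is symmetric", {
  w <- make_fixture("staining_columns")
  ids <- w$cells$id
  co <- cbind(w$cells$x, w$cells$y, w$cells$z)
  d <- sqrt(sum((co[1, ] - co[20, ])^2))
  expect_gt(d, 3 * max(w$cells$radius))
  expect_false(ids[20] %in% neighbours(w, ids[1]))
  nb1 <- neighbours(w, ids[1])
  for (j in nb1) expect_true(ids[1] %in% neighbours(w, j))
})

test_that("isolated cells read zero pressure; overlap increases it", {
  w <- make_fixture("staining_columns")
  # top cells are ~1 apart with radius ~0.45: some isolated contacts
  w2 <- make_fixture("overlap_pair")
  expect_gt(pressure(w2, w2$cells$id[1]), 0)
  # doubling the overlap strictly increases pressure
  r <- w2$cells$radius[1]
  p_before <- pressure(w2, w2$cells$id[1])
  # move cell 2 closer along the azimuth to double the overlap
  R <- w2$config$geometry$radius
  overlap <- 2 * r - 0.8 * 2 * r
  d_new <- 2 * r - 2 * overlap
  w2$cells$x[2] <- R * cos(d_new / R)
  w2$cells$y[2] <- R * sin(d_new / R)
  expect_gt(pressure(w2, w2$cells$id[1]), p_before)
})

test_that("symmetric overlapping pair relaxes symmetrically", {
  w <- make_fixture("overlap_pair")
  z0 <- w$cells$z
  az0 <- atan2(w$cells$y, w$cells$x)
  w2 <- relax(w, 0.02)
  az1 <- atan2(w2$cells$y, w2$cells$x)
  d0 <- az0[2] - az0[1]
  d1 <- az1[2] - az1[1]
  expect_gt(d1, d0)                         # pushed apart
  # displacements equal and opposite in azimuth
  expect_equal(az1[1] - az0[1], -(az1[2] - az0[2]), tolerance = 1e-6)
  expect_equal(w2$cells$z, z0, tolerance = 1e-6)
})

test_that("a single cell does not move during relaxation", {
  w <- make_fixture("overlap_pair")
  w <- remove_cells(w, 2L)
  pos0 <- c(w$cells$x, w$cells$y, w$cells$z)
  w2 <- relax(w, 0.1)
  expect_equal(c(w2$cells$x, w2$cells$y, w2$cells$z), pos0,
               tolerance = 1e-9)
})

test_that("Paneth cells displace less than stem cells under equal force", {
  w <- make_fixture("paneth_stem_pair")
  az0 <- atan2(w$cells$y, w$cells$x)
  w2 <- relax(w, 0.02)
  az1 <- atan2(w2$cells$y, w2$cells$x)
  disp_paneth <- abs(az1[1] - az0[1]) * w$config$geometry$radius
  disp_stem <- abs(az1[2] - az0[2]) * w$config$geometry$radius
  expect_gt(disp_stem, disp_paneth * 2)
})

test_that("daughters split mass, Wnt and BrdU exactly in half", {
  w <- make_fixture("overlap_pair")
  w$cells$wnt[1] <- 8; w$cells$brdu[1] <- 1; w$cells$mass[1] <- 2
  w$cells$type[1] <- CT_ABSORPTIVE_PROGENITOR
  w$cells$divisions[1] <- 2L
  id <- w$cells$id[1]
  w2 <- place_daughters(w, id)
  expect_false(id %in% w2$cells$id)
  d <- which(w2$cells$id %in% w2$last_daughters)
  expect_length(d, 2)
  expect_equal(w2$cells$wnt[d], c(4, 4))       # conserved exactly
  expect_equal(w2$cells$brdu[d], c(0.5, 0.5))
  expect_equal(w2$cells$mass[d], c(1, 1))
  expect_equal(w2$cells$divisions[d], c(3L, 3L))
})

test_that("motion direction uses dz outside and dtheta inside the niche", {
  w <- make_fixture("trajectory_pair")
  expect_equal(motion_direction(w, 1L, window = 2), "FORWARD")
  expect_equal(motion_direction(w, 2L, window = 2), "RETROGRADE")
  # stationary cell ties as FORWARD
  w$obs$traj <- lapply(w$obs$traj, function(r) { r$z <- c(2, 2); r$s <- r$s * 0 + 3; r })
  expect_equal(motion_direction(w, 1L, window = 2), "FORWARD")
  # niche cell with decreasing polar angle is retrograde even at the base
  w2 <- make_fixture("trajectory_pair")
  for (i in seq_along(w2$obs$traj)) {
    w2$obs$traj[[i]]$z <- c(-0.5, -0.5)
    w2$obs$traj[[i]]$theta <- c(1.0 - 0.1 * i, 1.0 + 0.1 * i)
  }
  expect_equal(motion_direction(w2, 1L, window = 2), "RETROGRADE")
  expect_equal(motion_direction(w2, 2L, window = 2), "FORWARD")
})

test_that("mini-crypt fixture satisfies the surface constraint everywhere", {
  w <- make_fixture("mini_crypt", seed = 2)
  res <- surface_residual(cbind(w$cells$x, w$cells$y, w$cells$z),
                          w$config$geometry)
  expect_lt(max(res), 1e-8)
  w2 <- run_world(w, 2)
  res2 <- surface_residual(cbind(w2$cells$x, w2$cells$y, w2$cells$z),
                           w2$config$geometry)
  expect_lt(max(res2), 1e-8)
})
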