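# Virtual experiments --------------------------------------------------------
#
# BrdU pulse-chase, Ki-67 staining, positional staining histograms scored
# the way mouse slides are scored (hemi-crypt columns), and retrograde
# motion statistics from recorded trajectories.

#' Schedule a BrdU pulse
#'
#' During the 120 min window after `t0` every cell in S-phase incorporates
#' the label permanently (`brdu = 1`); the label halves at each division
#' and is detectable while above the configured threshold (default 0.04,
#' between 1/32 and 1/16, so the label is lost after exactly five
#' divisions).
#'
#' @param world A `WorldState`.
#' @param t0 Injection time (h).
#' @return Updated world (labelling itself happens as the world steps
#'   through the window).
#' @export
brdu_pulse <- function(world, t0) {
  world$schedule$brdu_pulses <- c(world$schedule$brdu_pulses, t0)
  world
}

#' Is a BrdU label level detectable?
#'
#' @param brdu Label level(s) in `[0, 1]`.
#' @param config Simulation configuration.
#' @return Logical vector.
#' @export
brdu_detectable <- function(brdu, config = default_config()) {
  brdu > config$observers$th_brdu
}

#' Ki-67 staining read-out
#'
#' Default (figure-caption variant): positive for cycling cells in all
#' phases except G1, for differentiated cells whose last cycling activity
#' is within the staining memory (6 h), and for recently arrested cells.
#' With `observers$ki67_g1_positive = TRUE` continuously cycling cells
#' stain in G1 as well.
#'
#' @param world A `WorldState`.
#' @param t Evaluation time; defaults to the world clock.
#' @return Logical vector over cells (in row order).
#' @export
ki67_positive <- function(world, t = world$time) {
  obs <- world$config$observers
  cl <- world$cells
  cycling <- cl$cycling & !cl$apoptotic
  in_g1 <- world$cycle$phase == 1L
  pos <- cycling & (!in_g1 | isTRUE(obs$ki67_g1_positive))
  mem <- !cycling & !is.na(cl$ki67_memory) &
    (t - cl$ki67_memory) <= obs$ki67_memory_h
  arr <- cl$arrested & !is.na(cl$arrest_time) &
    (t - cl$arrest_time) <= obs$ki67_memory_h
  (pos | mem | arr) & !cl$apoptotic
}

#' Position index along hemi-crypt columns
#'
#' Splits the crypt into `observers$sectors` equal angular sectors (two
#' hemi-crypt columns by default, matching how mouse slides are scored)
#' and ranks cells within each sector by longitudinal arc length from the
#' crypt base.  Within a sector positions are a gap-free permutation
#' `1..n`.
#'
#' @param world A `WorldState`.
#' @return Data frame with `id`, `sector`, `position`.
#' @export
position_index <- function(world) {
  n <- length(world$cells$id)
  if (!n) {
    return(data.frame(id = integer(0), sector = integer(0),
                      position = integer(0)))
  }
  co <- surface_coords(cell_xyz(world), world$config$geometry)
  ns <- world$config$observers$sectors
  az <- atan2(world$cells$y, world$cells$x) %% (2 * pi)
  sector <- pmin(ns, 1L + floor(az / (2 * pi / ns)))
  pos <- integer(n)
  for (sct in unique(sector)) {
    idx <- which(sector == sct)
    pos[idx] <- rank(co$s[idx], ties.method = "first")
  }
  data.frame(id = world$cells$id, sector = sector, position = pos)
}

#' Per-position staining fractions
#'
#' For each position index, the fraction of hemi-crypt columns whose cell
#' at that position satisfies the predicate.
#'
#' @param world A `WorldState`.
#' @param predicate Logical vector over cells (row order), or a function
#'   of the world returning one.
#' @return Data frame with `position`, `fraction`, `n` (columns scored).
#' @export
positional_fraction <- function(world, predicate) {
  if (is.function(predicate)) predicate <- predicate(world)
  pidx <- position_index(world)
  if (!nrow(pidx)) {
    return(data.frame(position = integer(0), fraction = numeric(0),
                      n = integer(0)))
  }
  agg <- stats::aggregate(predicate,
                          by = list(position = pidx$position), FUN = mean)
  cnt <- stats::aggregate(predicate,
                          by = list(position = pidx$position), FUN = length)
  data.frame(position = agg$position, fraction = agg$x, n = cnt$x)
}

#' Motion direction of a cell over a trailing window
#'
#' Outside the hemispherical niche a cell moves RETROGRADE iff its mean
#' longitudinal velocity dz/dt is negative; inside the niche iff the mean
#' rate of change of its polar angle is negative (theta increases towards
#' the villus), so retrograde motion can be recorded even at the crypt
#' base.  Zero net velocity counts as FORWARD (tie-break).
#'
#' @param world A `WorldState` with recorded trajectories.
#' @param cell_id Cell id.
#' @param window Trailing window (h).
#' @return `"FORWARD"`, `"RETROGRADE"`, or `NA` if fewer than two
#'   positions are recorded in the window.
#' @export
motion_direction <- function(world, cell_id, window = 2) {
  tr <- trajectory_of(world, cell_id, window)
  if (is.null(tr) || nrow(tr) < 2L) return(NA_character_)
  classify_motion(tr$time, tr$z, tr$theta)
}

classify_motion <- function(time, z, theta) {
  dt <- diff(range(time))
  if (dt <= 0) return(NA_character_)
  dz <- (z[length(z)] - z[1L]) / dt
  dth <- (theta[length(theta)] - theta[1L]) / dt
  in_cap <- mean(z) <= 0
  v <- if (in_cap) dth else dz
  if (v < 0) "RETROGRADE" else "FORWARD"
}

trajectory_of <- function(world, cell_id, window) {
  recs <- world$obs$traj
  if (!length(recs)) return(NULL)
  t_now <- world$time
  out <- list()
  for (r in recs) {
    if (r$time < t_now - window) next
    k <- match(cell_id, r$id)
    if (is.na(k)) next
    out[[length(out) + 1L]] <- c(r$time, r$z[k], r$theta[k], r$s[k])
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  data.frame(time = m[, 1L], z = m[, 2L], theta = m[, 3L], s = m[, 4L])
}

#' Forward/retrograde frequency by crypt position
#'
#' Classifies every recorded cell-interval in the window by motion
#' direction (see [motion_direction()]) and tabulates the forward and
#' retrograde fractions per position (longitudinal arc-length bin of one
#' cell diameter).  Fractions sum to 1 at every position with data.
#'
#' @param world A `WorldState` with recorded trajectories.
#' @param window Trailing window (h).
#' @return Data frame with `position`, `forward`, `retrograde`, `n`.
#' @export
retrograde_frequency <- function(world, window = Inf) {
  recs <- world$obs$traj
  if (length(recs) < 2L) {
    return(data.frame(position = integer(0), forward = numeric(0),
                      retrograde = numeric(0), n = integer(0)))
  }
  t_now <- world$time
  recs <- Filter(function(r) r$time >= t_now - window, recs)
  if (length(recs) < 2L) {
    return(data.frame(position = integer(0), forward = numeric(0),
                      retrograde = numeric(0), n = integer(0)))
  }
  pos <- integer(0); retro <- logical(0)
  for (i in seq_len(length(recs) - 1L)) {
    a <- recs[[i]]; b <- recs[[i + 1L]]
    common <- intersect(a$id, b$id)
    if (!length(common)) next
    ka <- match(common, a$id); kb <- match(common, b$id)
    dt <- b$time - a$time
    if (dt <= 0) next
    in_cap <- (a$z[ka] + b$z[kb]) / 2 <= 0
    v <- ifelse(in_cap, b$theta[kb] - a$theta[ka], b$z[kb] - a$z[ka]) / dt
    pos <- c(pos, pmax(1L, ceiling(a$s[ka])))
    retro <- c(retro, v < 0)
  }
  if (!length(pos)) {
    return(data.frame(position = integer(0), forward = numeric(0),
                      retrograde = numeric(0), n = integer(0)))
  }
  tab <- stats::aggregate(retro, by = list(position = pos), FUN = mean)
  cnt <- stats::aggregate(retro, by = list(position = pos), FUN = length)
  data.frame(position = tab$position, forward = 1 - tab$x,
             retrograde = tab$x, n = cnt$x)
}
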