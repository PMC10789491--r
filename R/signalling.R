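# Signalling: Wnt tethering, Notch lateral inhibition, BMP gradient --------

#' ZNRF3/RNF43-like feedback factor
#'
#' Wnt tethering is attenuated when the stem-cell count exceeds its
#' homeostatic value `n_star`: `phi = min(1, (n_star / stem_count)^h)`.
#' At or below `n_star` the factor is 1.
#'
#' @param stem_count Current number of stem cells.
#' @param n_star Homeostatic stem count.
#' @param h Hill exponent (>= 1).
#' @return Feedback factor in (0, 1].
#' @export
znrf3_feedback <- function(stem_count, n_star, h = 2) {
  if (stem_count <= 0) return(1)
  min(1, (n_star / stem_count)^h)
}

#' Update tethered Wnt for all cells
#'
#' Wnt sources are the Paneth cells and a fixed mesenchymal emitter ring
#' on the niche hemisphere.  Each cell within range `r_wnt` of a source
#' tethers Wnt at `k_tether * phi` per source per hour, weighted by a
#' smooth emission kernel that declines with distance and is exactly zero
#' beyond `r_wnt` (additive over sources).  The spatial grading makes
#' stem renewal a graded function of depth in the niche.  Tethered Wnt is never removed except by division splitting,
#' so cells migrating away from the sources deplete it only as they divide.
#' The ZNRF3-like feedback factor `phi` can be forced to 1 with the
#' `feedback` argument (knockout experiments).
#'
#' @param world A `WorldState`.
#' @param dt Step (h).
#' @param feedback Logical; `FALSE` disables the niche feedback.
#' @return Updated world.
#' @export
update_wnt <- function(world, dt, feedback = TRUE) {
  sig <- world$config$signalling
  cl <- world$cells
  n <- length(cl$x)
  if (n == 0L) return(world)
  xyz <- cell_xyz(world)
  alive <- !cl$apoptotic
  stem_count <- world$stats$stem_count_avg %||%
    sum(cl$type == CT_STEM & alive)
  phi <- if (feedback) {
    znrf3_feedback(stem_count, sig$n_star, sig$h_feedback)
  } else 1
  # emission kernel: smooth decline with distance, zero beyond r_wnt
  kern <- function(d) ifelse(d < sig$r_wnt,
                             exp(-3 * (d / sig$r_wnt)^2), 0)
  src <- numeric(n)
  # mesenchymal ring
  src <- src + kern(ring_distance(xyz, world$config$geometry,
                                  sig$mesench_theta))
  # Paneth sources: each Paneth cell has a fixed ligand emission budget
  # per hour, split among the receptive cells in its range, so adding
  # Paneth cells adds Wnt sub-linearly (ligand conservation)
  pan <- which(cl$type == CT_PANETH & alive)
  for (k in pan) {
    d <- sqrt((xyz[, 1L] - xyz[k, 1L])^2 + (xyz[, 2L] - xyz[k, 2L])^2 +
                (xyz[, 3L] - xyz[k, 3L])^2)
    contrib <- kern(d)
    contrib[k] <- 0              # a Paneth cell is not its own source
    tot <- sum(contrib)
    if (tot > 1e-9) {
      src <- src + contrib / tot * min(tot, sig$paneth_emission)
    }
  }
  src <- pmin(src, sig$src_cap %||% Inf)   # receptor-limited tethering
  world$cells$wnt <- cl$wnt + sig$k_tether * phi * src * dt
  world
}

#' Update Notch activation for all cells
#'
#' Notch accumulates from contacting Delta presenters (the secretory
#' types: Paneth, secretory progenitor, goblet, enteroendocrine) at
#' `k_notch` per presenter per hour and decays first-order at
#' `lambda_notch`; the steady state with `m` presenters is
#' `k_notch * m / lambda_notch`.
#'
#' @param world A `WorldState`.
#' @param dt Step (h).
#' @return Updated world.
#' @export
update_notch <- function(world, dt) {
  sig <- world$config$signalling
  m <- secretory_neighbour_count(world)
  world$cells$notch <- world$cells$notch +
    (sig$k_notch * m - sig$lambda_notch * world$cells$notch) * dt
  world
}

#' Evaluate the BMP signal at axial positions
#'
#' `B(z, t) = bmp_beta * E(t) * g(z) * a(z)` where `E(t)` is the current
#' enterocyte count on the villus, `g` is a normalized logistic profile
#' increasing in `z`, and `a(z) = bmp_a_min` inside the antagonist zone
#' around the niche (z below `bmp_antagonist_zone`), 1 elsewhere.  The
#' enterocyte coupling makes the gradient a negative feedback loop: fewer
#' enterocytes lower BMP everywhere, letting progenitors divide and migrate
#' further up before differentiating.
#'
#' @param world A `WorldState`.
#' @param z Axial position(s).
#' @return BMP level(s) (A.U.).
#' @export
evaluate_bmp <- function(world, z) {
  sig <- world$config$signalling
  E <- villus_enterocyte_count(world)
  g <- 1 / (1 + exp(-(z - sig$bmp_z_half) / sig$bmp_width))
  a <- ifelse(z <= sig$bmp_antagonist_zone, sig$bmp_a_min, 1)
  sig$bmp_beta * E * g * a
}
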