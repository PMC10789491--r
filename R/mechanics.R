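# Off-lattice cell-centre mechanics ----------------------------------------
#
# Cells are overlapping spheres constrained to the crypt surface.  Pairs
# closer than the sum of their radii interact through a linear (Hookean)
# overlap spring with type-dependent stiffness; motion is overdamped with
# drag proportional to stiffness, so Paneth cells (stiffer and larger)
# displace less under equal force.  Intercellular pressure is the
# stiffness-weighted sum of positive overlaps and feeds contact inhibition
# of proliferation through the p27 production rate.

cell_xyz <- function(world) {
  cbind(world$cells$x, world$cells$y, world$cells$z, deparse.level = 0L)
}

# All contact pairs: list(i, j, dist, overlap) with i < j (row indices).
contact_pairs <- function(world) {
  n <- length(world$cells$x)
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0),
                dist = numeric(0), overlap = numeric(0)))
  }
  .contact_pairs_cpp(cell_xyz(world), world$cells$radius,
                     world$config$mechanics$contact_factor)
}

#' Neighbours of a cell
#'
#' Cells whose centre distance is below `contact_factor` times the sum of
#' radii.  The relation is symmetric and excludes the cell itself.
#'
#' @param world A `WorldState`.
#' @param cell_id Cell id.
#' @return Integer vector of neighbouring cell ids.
#' @export
neighbours <- function(world, cell_id) {
  k <- match(cell_id, world$cells$id)
  if (is.na(k)) stop("no such cell: ", cell_id)
  p <- contact_pairs(world)
  nb <- c(p$j[p$i == k], p$i[p$j == k])
  world$cells$id[nb]
}

# Per-cell count of neighbouring Delta presenters (secretory types).
secretory_neighbour_count <- function(world) {
  n <- length(world$cells$x)
  cnt <- integer(n)
  if (n < 2L) return(cnt)
  p <- contact_pairs(world)
  sec <- world$cells$type %in% SECRETORY_TYPES
  cnt <- cnt + tabulate(p$i[sec[p$j]], nbins = n)
  cnt + tabulate(p$j[sec[p$i]], nbins = n)
}

#' Intercellular pressure readings
#'
#' Pressure on a cell is the sum over contacting neighbours of the positive
#' overlap weighted by the contact stiffness of the pair (product of the
#' two cells' relative stiffness factors, so contacts with stiff Paneth
#' cells dominate the niche reading).  An isolated cell reads 0.
#'
#' @param world A `WorldState`.
#' @param cell_id Optional id; default returns the vector for all cells.
#' @return Numeric vector of pressures (A.U.), in cell order (or length 1).
#' @export
pressure <- function(world, cell_id = NULL) {
  n <- length(world$cells$x)
  pr <- numeric(n)
  if (n >= 2L) {
    p <- contact_pairs(world)
    w <- world$cells$stiffness[p$i] * world$cells$stiffness[p$j]
    contrib <- pmax(0, p$overlap) * w
    pr <- tabulate2(p$i, contrib, n) + tabulate2(p$j, contrib, n)
  }
  if (is.null(cell_id)) return(pr)
  k <- match(cell_id, world$cells$id)
  if (is.na(k)) stop("no such cell: ", cell_id)
  pr[k]
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  if (length(idx)) {
    agg <- rowsum(w, idx)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Mechanical relaxation
#'
#' Advances overdamped cell-centre motion for `dt` hours in sub-steps of
#' `mechanics$dt_mech`: each cell moves by net spring force divided by its
#' drag, then is projected back onto the crypt surface.  The pair force is
#' a linear overlap spring inside contact plus a short-range adhesive well
#' just outside it (cohesive epithelium).  Drag is proportional to
#' stiffness, so stiff (Paneth) cells are harder to displace.
#'
#' @param world A `WorldState`.
#' @param dt Time to relax (h).
#' @return The updated world.
#' @export
relax <- function(world, dt) {
  mech <- world$config$mechanics
  n <- length(world$cells$x)
  if (n < 2L || dt <= 0) return(world)
  nsub <- max(1L, ceiling(dt / mech$dt_mech))
  h <- dt / nsub
  geom <- world$config$geometry
  pan <- world$cells$type == CT_PANETH
  # Paneth cells are matrix-anchored at the crypt base
  drag <- world$cells$stiffness * ifelse(pan, mech$paneth_anchor, 1)
  out <- .relax_cpp(cell_xyz(world), world$cells$radius,
                    world$cells$stiffness, mech$k_spring, h, nsub,
                    mech$max_disp, geom$radius, geom$height,
                    mech$k_adhesion, mech$adhesion_range,
                    pan, mech$paneth_rest_factor, drag)
  if (!isTRUE(out$ok)) {
    stop("mechanical step unstable: displacement ",
         signif(out$max_disp, 3), " exceeds ", mech$max_disp,
         " per sub-step; reduce dt_mech or k_spring")
  }
  X <- out$X
  world$cells$x <- X[, 1L]; world$cells$y <- X[, 2L]
  world$cells$z <- X[, 3L]
  world
}

#' Place two daughters of a dividing mother
#'
#' Daughters appear at the mother's position displaced by `division_sep`
#' in opposite directions along a random surface tangent.  Mass, tethered
#' Wnt and BrdU label are split exactly in half; the mother's id is retired
#' and never reused.  For committed progenitors the division counter is
#' incremented.
#'
#' @param world A `WorldState`.
#' @param mother_id Id of the dividing cell.
#' @return The updated world (invisibly carries the new ids in
#'   `world$last_daughters`).
#' @export
place_daughters <- function(world, mother_id) {
  k <- match(mother_id, world$cells$id)
  if (is.na(k)) stop("no such cell: ", mother_id)
  world <- add_daughters(world, k)
  world <- remove_cells(world, match(mother_id, world$cells$id))
  world
}

# internal: append two daughters for mother row k (does not remove mother)
add_daughters <- function(world, k) {
  cfg <- world$config
  pos <- cell_xyz(world)[k, , drop = FALSE]
  tang <- surface_tangent(pos, cfg$geometry)
  eps <- cfg$mechanics$division_sep
  p1 <- surface_project(pos + eps * tang, cfg$geometry)
  p2 <- surface_project(pos - eps * tang, cfg$geometry)
  cl <- world$cells
  ids <- world$next_id + c(0L, 1L)
  world$next_id <- world$next_id + 2L
  type <- cl$type[k]
  divs <- if (type == CT_ABSORPTIVE_PROGENITOR || type == CT_SECRETORY_PROGENITOR) {
    cl$divisions[k] + 1L
  } else 0L
  q0 <- world$cycle$q[k]
  for (d in 1:2) {
    p <- if (d == 1L) p1 else p2
    world <- append_cell(
      world, id = ids[d], type = type,
      x = p[1L], y = p[2L], z = p[3L],
      mass = cl$mass[k] / 2, wnt = cl$wnt[k] / 2, notch = cl$notch[k],
      brdu = cl$brdu[k] / 2, dna = cl$dna[k], rna = cl$rna[k],
      divisions = divs, birth_time = world$time,
      cycling = TRUE, q = q0
    )
  }
  world$last_daughters <- ids
  world
}
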