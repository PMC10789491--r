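# Villus compartment ---------------------------------------------------------
#
# The villus is a one-dimensional conveyor of cell records fed by cells
# exiting the crypt mouth.  Records keep type and entry time; axial order
# is entry order.  Tip shedding is residence-time based: a cell is shed
# once its time on the villus exceeds the homeostatic transit time, so
# shedding continues (and the villus shrinks) when crypt influx collapses,
# with the delayed-minimum dynamics seen after crypt injury.

villus_init <- function(types = integer(0), entry = numeric(0),
                        transit_h = 72) {
  list(type = as.integer(types), entry = as.numeric(entry),
       transit_h = transit_h)
}

#' Number of enterocytes currently on the villus
#'
#' Drives the BMP feedback.  With `include_crypt = TRUE` (configuration
#' flag) crypt-resident mature enterocytes are added.
#'
#' @param world A `WorldState`.
#' @return Integer count.
#' @export
villus_enterocyte_count <- function(world) {
  n <- sum(world$villus$type == CT_ENTEROCYTE)
  if (isTRUE(world$config$geometry$include_crypt_enterocytes)) {
    n <- n + sum(world$cells$type == CT_ENTEROCYTE & !world$cells$apoptotic)
  }
  n
}

#' Transfer crypt-exiting cells to the villus and shed at the tip
#'
#' Cells at the crypt mouth (within half a cell diameter of `z = height`)
#' leave the crypt and enqueue at the villus base (logged as
#' `villus_transfer`); villus records older than the transit time are shed
#' from the tip (logged as `shedding`).
#'
#' @param world A `WorldState`.
#' @param dt Step (h).
#' @return Updated world.
#' @export
transfer_and_shed <- function(world, dt) {
  H <- world$config$geometry$height
  leaving <- which(world$cells$z >= H - 0.5 & !world$cells$apoptotic)
  if (length(leaving)) {
    for (k in leaving) {
      world <- log_event(world, "villus_transfer", world$cells$id[k],
                         world$cells$type[k])
    }
    world$villus$type <- c(world$villus$type, world$cells$type[leaving])
    world$villus$entry <- c(world$villus$entry, rep(world$time,
                                                    length(leaving)))
    world <- remove_cells(world, leaving)
  }
  shed <- world$time - world$villus$entry > world$villus$transit_h
  if (any(shed)) {
    world$stats$shed_count <- world$stats$shed_count + sum(shed)
    world <- log_event(world, "shedding", NA_integer_, NA_integer_,
                       detail = as.character(sum(shed)))
    world$villus$type <- world$villus$type[!shed]
    world$villus$entry <- world$villus$entry[!shed]
  }
  world
}
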