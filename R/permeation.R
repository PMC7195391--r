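ELEMENTARY_CHARGE <- 1.602176634e-19  # C (CODATA)

#' Transmembrane voltage from an applied field
#'
#' Under a constant electrostatic field E along the membrane normal, the
#' transmembrane voltage is V = E x L with L the box z-dimension.
#'
#' @param E applied field in V/nm
#' @param L box z-dimension in nm
#' @return voltage in mV
#' @examples
#' voltage_from_field(0.0325, 9.2308)  # 300 mV
#' @export
voltage_from_field <- function(E, L) {
  if (any(L <= 0)) stop("L must be > 0")
  E * L * 1000
}

#' Selectivity-filter slab bounds per frame
#'
#' The filter slab is bounded below by the mean z of the Thr59 O-gamma
#' atoms minus `margin` and above by the mean z of the topmost filter
#' carbonyl oxygens plus `margin`. A permeation event requires full
#' traversal of this slab.
#'
#' @inheritParams hbond_distance
#' @param margin slab margin in nm
#' @return `n_frames x 2` matrix with columns `z_low`, `z_high`
#' @export
filter_bounds <- function(frames, topology, margin = 0.1,
                          config = channel_config()) {
  z_og <- plane_z(frames, topology,
                  sprintf("resid %d and name OG1", config$thr59))
  z_top <- plane_z(frames, topology,
                   sprintf("resid %d and name O", config$filter_resids[2]))
  out <- cbind(z_low = z_og - margin, z_high = z_top + margin)
  if (any(out[, 1] >= out[, 2]))
    stop("filter bounds inverted (z_low >= z_high); check the topology")
  out
}

#' Detect filter-crossing events of one ion
#'
#' Three-compartment automaton over an unwrapped z series: frames are
#' classified below / inside / above the filter slab; a +1 (outward) event
#' is recorded when the ion's visited-compartment history completes
#' below -> inside -> above, a -1 event for the reverse. Bounces and
#' re-entries without full traversal count nothing, and events never
#' overlap.
#'
#' @param ion_z continuous (unwrapped) per-frame z series of one ion, or a
#'   matrix with one column per ion
#' @param bounds `n_frames x 2` matrix (`z_low`, `z_high`) from
#'   [filter_bounds()], or a length-2 vector recycled over frames
#' @param ion_id id(s) recorded in the output
#' @return data.frame with columns `ion_id`, `entry_frame`, `exit_frame`
#'   (1-based), `direction` (+1 outward, -1 inward)
#' @export
detect_permeation_events <- function(ion_z, bounds, ion_id = NULL) {
  if (is.matrix(ion_z)) {
    ids <- ion_id %||% seq_len(ncol(ion_z))
    out <- lapply(seq_len(ncol(ion_z)), function(i)
      detect_permeation_events(ion_z[, i], bounds, ids[i]))
    return(do.call(rbind, out))
  }
  stop_if_not_finite(ion_z, "ion_z")
  nf <- length(ion_z)
  if (is.null(dim(bounds))) bounds <- matrix(bounds, nf, 2L, byrow = TRUE)
  stop_if_not_finite(bounds, "bounds")
  comp <- ifelse(ion_z < bounds[, 1L], -1L, ifelse(ion_z > bounds[, 2L], 1L, 0L))
  events <- list()
  side <- 0L          # last non-inside compartment visited
  entry <- NA_integer_  # frame at which the slab was entered from `side`
  for (f in seq_len(nf)) {
    cf <- comp[f]
    if (cf == 0L) {
      if (side != 0L && is.na(entry)) entry <- f
    } else if (side == 0L) {
      side <- cf
      entry <- NA_integer_
    } else if (cf == side) {
      entry <- NA_integer_   # bounced back without traversal
    } else {
      if (!is.na(entry)) {
        events[[length(events) + 1L]] <-
          data.frame(ion_id = ion_id %||% 1L, entry_frame = entry,
                     exit_frame = f, direction = cf)
      }
      side <- cf
      entry <- NA_integer_
    }
  }
  if (length(events) == 0L)
    return(data.frame(ion_id = integer(), entry_frame = integer(),
                      exit_frame = integer(), direction = integer()))
  do.call(rbind, events)
}

#' Current from net permeation events
#'
#' One elementary charge crosses per event: I = (n_plus - n_minus) e /
#' t_total. 39 net events per microsecond correspond to 6.25 pA.
#'
#' @param n_plus,n_minus outward and inward event counts
#' @param t_total_ns total simulated time in ns
#' @return current in pA
#' @export
current_from_events <- function(n_plus, n_minus, t_total_ns) {
  if (any(t_total_ns <= 0)) stop("t_total_ns must be > 0")
  (n_plus - n_minus) * ELEMENTARY_CHARGE / (t_total_ns * 1e-9) * 1e12
}

#' Replicate statistics for currents
#'
#' @param per_replicate numeric vector of per-replicate currents (pA)
#' @return list of class `current_estimate` with `values`, `mean`, `sem`
#'   (NA for a single replicate, never 0) and `n`
#' @export
aggregate_current <- function(per_replicate) {
  if (length(per_replicate) == 0L) stop("no replicates")
  structure(list(values = per_replicate, mean = mean(per_replicate),
                 sem = sem(per_replicate), n = length(per_replicate)),
            class = "current_estimate")
}

#' @export
print.current_estimate <- function(x, ...) {
  cat(sprintf("<current_estimate> %.3g +/- %.3g pA (sem, n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Potassium occupancy of the filter binding sites
#'
#' Sites S1-S4 are the slabs between consecutive backbone carbonyl-oxygen
#' planes of the filter residues (S4 lowest, between the Thr59 and Val60
#' carbonyl planes); Scav is the slab between the Phe87 C-alpha plane and
#' the Thr59 O-gamma plane. A site is occupied in a frame when at least one
#' selected ion lies inside the slab and within `axis_radius` of the pore
#' axis.
#'
#' @inheritParams hbond_distance
#' @param ion_expression selection for the permeant ions
#' @param axis_radius cylinder radius around the pore axis (nm)
#' @return named numeric vector of fractional occupancies (S1..S4, Scav)
#' @export
site_occupancy <- function(frames, topology, ion_expression = "resname K",
                           axis_radius = 0.4, config = channel_config()) {
  resids <- seq(config$filter_resids[1], config$filter_resids[2])
  planes <- sapply(resids, function(r)
    plane_z(frames, topology, sprintf("resid %d and name O", r)))
  planes <- matrix(planes, ncol = length(resids))
  if (any(apply(planes, 1L, diff) <= 0))
    stop("filter carbonyl planes out of order")
  z_og <- plane_z(frames, topology, sprintf("resid %d and name OG1", config$thr59))
  z_cav <- plane_z(frames, topology, sprintf("resid %d and name CA", config$phe87))
  sel <- select(topology, ion_expression)
  nf <- n_frames(frames)
  occ <- setNames(numeric(5L), c("S1", "S2", "S3", "S4", "Scav"))
  if (length(sel$indices) == 0L) return(occ)
  axis <- pore_axis(frames, topology, config)
  ions <- frames$coords[sel$indices + 1L, , , drop = FALSE]
  for (f in seq_len(nf)) {
    xy <- ions[, 1:2, f, drop = FALSE]
    r <- sqrt((xy[, 1, 1] - axis[1, f])^2 + (xy[, 2, 1] - axis[2, f])^2)
    z <- ions[, 3, f]
    near <- r <= axis_radius
    # sites count down from the top: S1 between the two topmost planes
    ns <- length(resids) - 1L
    for (k in seq_len(min(4L, ns))) {
      lo <- planes[f, ns + 1L - k]
      hi <- planes[f, ns + 2L - k]
      site <- paste0("S", k)
      occ[site] <- occ[site] + any(near & z >= lo & z < hi)
    }
    occ["Scav"] <- occ["Scav"] + any(near & z >= z_cav[f] & z < z_og[f])
  }
  occ / nf
}
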