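#' Axial density profile along the permeation pathway
#'
#' Counts selected atoms inside a cylinder around the pore axis, binned
#' along z and averaged over frames. z is measured relative to the Thr59
#' O-gamma plane (z = 0), so profiles from different replicates and systems
#' superpose; the whole profile is invariant under rigid z-translation of
#' the system.
#'
#' @inheritParams hbond_distance
#' @param expression selection of the profiled species (e.g. "resname K"
#'   or "name OW")
#' @param axis_radius cylinder radius (nm)
#' @param bin_width z bin width (nm)
#' @param z_range length-2 interval (nm, relative to the O-gamma plane)
#' @return object of class `axial_profile`: `z_centers`, `density`
#'   (mean counts per frame per bin), raw `counts`, `n_frames`, and a
#'   placeholder `F` filled by [free_energy_profile()]
#' @export
axial_density <- function(frames, topology, expression,
                          axis_radius = 0.5, bin_width = 0.05,
                          z_range = c(-2, 2), config = channel_config()) {
  stopifnot(bin_width > 0, length(z_range) == 2L, z_range[1] < z_range[2])
  nf <- n_frames(frames)
  if (nf == 0L) stop("zero frames")
  sel <- select(topology, expression)
  if (length(sel$indices) == 0L) stop("empty selection: ", expression)
  z_ref <- plane_z(frames, topology,
                   sprintf("resid %d and name OG1", config$thr59))
  axis <- pore_axis(frames, topology, config)
  breaks <- seq(z_range[1], z_range[2] + bin_width / 2, by = bin_width)
  counts <- numeric(length(breaks) - 1L)
  sub <- frames$coords[sel$indices + 1L, , , drop = FALSE]
  for (f in seq_len(nf)) {
    dx <- sub[, 1L, f] - axis[1L, f]
    dy <- sub[, 2L, f] - axis[2L, f]
    zrel <- sub[, 3L, f] - z_ref[f]
    inside <- (dx^2 + dy^2) <= axis_radius^2
    zin <- zrel[inside]
    ix <- findInterval(zin, breaks)
    ix <- ix[ix >= 1L & ix <= length(counts)]
    if (length(ix)) {
      t <- tabulate(ix, nbins = length(counts))
      counts <- counts + t
    }
  }
  structure(list(z_centers = (breaks[-1L] + head(breaks, -1L)) / 2,
                 counts = counts, density = counts / nf, n_frames = nf,
                 F = NULL, species = expression),
            class = "axial_profile")
}

#' "Free energy" profile by Boltzmann inversion
#'
#' F(z) = -ln(density(z) / max density) in kBT units, so the minimum is 0
#' at the most populated bin. Bins with zero density are masked (NA), never
#' reported as 0 or infinity. The quotation marks are deliberate: under an
#' applied voltage the ensemble is not at equilibrium, so this is an
#' effective, not a thermodynamic, free energy.
#'
#' @param profile an `axial_profile` from [axial_density()]
#' @return the profile with `F` filled (kBT)
#' @export
free_energy_profile <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  if (all(profile$density == 0)) stop("all-zero density: cannot invert")
  dmax <- max(profile$density)
  F <- -log(profile$density / dmax)
  F[profile$density == 0] <- NA_real_
  profile$F <- F
  profile
}

#' Barrier height from a "free energy" profile
#'
#' Maximum F inside `region` minus a reference level: the mean F over the
#' `reference` interval when given, else 0 (the profile minimum, since F is
#' normalized to min 0). Only differences are meaningful because the
#' profile zero is a normalization choice.
#'
#' @param profile an `axial_profile` with `F` filled
#' @param region length-2 z interval (nm) containing the barrier
#' @param reference optional length-2 z interval used as the reference level
#' @return barrier height in kBT
#' @export
barrier_height <- function(profile, region, reference = NULL) {
  stopifnot(inherits(profile, "axial_profile"), !is.null(profile$F))
  zin <- profile$z_centers >= region[1] & profile$z_centers <= region[2]
  Fin <- profile$F[zin]
  if (all(!is.finite(Fin))) stop("region is fully masked")
  ref <- 0
  if (!is.null(reference)) {
    rin <- profile$z_centers >= reference[1] & profile$z_centers <= reference[2]
    Fr <- profile$F[rin]
    if (all(!is.finite(Fr))) stop("reference interval is fully masked")
    ref <- mean(Fr[is.finite(Fr)])
  }
  max(Fin, na.rm = TRUE) - ref
}

#' Pore-radius profile
#'
#' For each z-slice, the pore radius is the minimum over nearby heavy atoms
#' of (xy-distance to the pore axis minus the atom's van der Waals radius),
#' clamped to [0, r_max] and averaged over frames. Slices are taken on the
#' fixed per-frame pore axis by default; `optimize_center = TRUE` grid
#' searches a local xy centre per slice (HOLE-like, without full sphere
#' propagation). Slices with no atoms nearby report `r_max` and are
#' flagged.
#'
#' @inheritParams hbond_distance
#' @param expression selection of the confining atoms (default: everything
#'   except ions, waters and lipids)
#' @param bin_width slice spacing (nm)
#' @param slab_half_width half-width of the atom slab per slice (nm)
#' @param r_max radius cap (nm)
#' @param z_range z interval relative to the Thr59 O-gamma plane (nm)
#' @param optimize_center optimize the slice centre on a 0.02 nm xy grid
#' @param stride analyze every `stride`-th frame
#' @return object of class `pore_profile`: `z_centers`, `radius` (nm),
#'   `empty_fraction` per slice
#' @export
pore_radius_profile <- function(frames, topology, expression = NULL,
                                bin_width = 0.05, slab_half_width = 0.15,
                                r_max = 1.5, z_range = c(-2, 0.5),
                                optimize_center = FALSE, stride = 1L,
                                config = channel_config()) {
  expression <- expression %||%
    sprintf("not (resname %s or resname %s or name %s) and not element H",
            config$ion_resname, config$water_resname, config$phosphate_name)
  sel <- select(topology, expression)
  if (length(sel$indices) == 0L) stop("empty selection: ", expression)
  vdw <- topology$atoms$vdw_radius[sel$indices + 1L]
  z_ref <- plane_z(frames, topology,
                   sprintf("resid %d and name OG1", config$thr59))
  axis <- pore_axis(frames, topology, config)
  zc <- seq(z_range[1], z_range[2], by = bin_width)
  keep <- seq(1L, n_frames(frames), by = stride)
  rsum <- numeric(length(zc))
  nempty <- integer(length(zc))
  offsets <- if (optimize_center)
    as.matrix(expand.grid(dx = seq(-0.2, 0.2, 0.02), dy = seq(-0.2, 0.2, 0.02)))
  else matrix(0, 1L, 2L)
  sub <- frames$coords[sel$indices + 1L, , , drop = FALSE]
  for (f in keep) {
    x <- sub[, 1L, f]; y <- sub[, 2L, f]
    zrel <- sub[, 3L, f] - z_ref[f]
    for (k in seq_along(zc)) {
      near <- abs(zrel - zc[k]) <= slab_half_width
      if (!any(near)) {
        rsum[k] <- rsum[k] + r_max
        nempty[k] <- nempty[k] + 1L
        next
      }
      best <- -Inf
      for (o in seq_len(nrow(offsets))) {
        cx <- axis[1L, f] + offsets[o, 1L]
        cy <- axis[2L, f] + offsets[o, 2L]
        r <- min(sqrt((x[near] - cx)^2 + (y[near] - cy)^2) - vdw[near])
        if (r > best) best <- r
      }
      rsum[k] <- rsum[k] + max(0, min(r_max, best))
    }
  }
  structure(list(z_centers = zc, radius = rsum / length(keep),
                 empty_fraction = nempty / length(keep), r_max = r_max),
            class = "pore_profile")
}

#' Membrane thickness from phosphate layers
#'
#' Per frame, phosphates are split into leaflets by z relative to their
#' mean; the thickness is the difference of the leaflet mean z positions,
#' averaged over frames with its SEM.
#'
#' @inheritParams hbond_distance
#' @param expression selection of the phosphate atoms
#' @return list of class `membrane_geometry`: `thickness` (nm), `sem`,
#'   `per_frame`
#' @export
membrane_thickness <- function(frames, topology, expression = "name P",
                               config = channel_config()) {
  sel <- select(topology, expression)
  if (length(sel$indices) == 0L) stop("no phosphate atoms selected")
  z <- frames$coords[sel$indices + 1L, 3L, , drop = FALSE]
  nf <- n_frames(frames)
  th <- numeric(nf)
  for (f in seq_len(nf)) {
    zf <- z[, 1L, f]
    upper <- zf > mean(zf)
    if (all(upper) || !any(upper))
      stop("bilayer error: all phosphates in one leaflet")
    th[f] <- mean(zf[upper]) - mean(zf[!upper])
  }
  structure(list(thickness = mean(th), sem = sem(th), per_frame = th),
            class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf("<membrane_geometry> thickness %.3f +/- %.3g nm (sem)\n",
              x$thickness, x$sem))
  invisible(x)
}
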