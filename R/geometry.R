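# Shared periodic-geometry helpers. All descriptor distances use the
# minimum-image convention in an orthorhombic box.

# Minimum-image displacement: d and box are 3 x n_frames matrices.
min_image <- function(d, box) d - box * round(d / box)

# Per-frame positions of one atom: 3 x n_frames matrix.
atom_track <- function(frames, atom_id) {
  matrix(frames$coords[atom_id + 1L, , ], nrow = 3L)
}

#' Per-frame minimum-image distance between two atoms
#' @param frames a [frame_series]
#' @param id_a,id_b 0-based atom ids
#' @param minimum_image apply the minimum-image convention (default TRUE)
#' @return numeric vector, one distance (nm) per frame
#' @export
pair_distance <- function(frames, id_a, id_b, minimum_image = TRUE) {
  d <- atom_track(frames, id_a) - atom_track(frames, id_b)
  if (minimum_image) d <- min_image(d, t(frames$box))
  sqrt(colSums(d^2))
}

# Mass-weighted centre of mass of an atom set, per frame: 3 x n_frames.
com_track <- function(frames, topology, atom_ids) {
  idx <- atom_ids + 1L
  m <- element_mass(topology$atoms$element[idx])
  w <- m / sum(m)
  sub <- frames$coords[idx, , , drop = FALSE]
  apply(sub * w, c(2L, 3L), sum)
}

# Distance between two per-frame points (3 x n_frames matrices).
point_distance <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) d <- min_image(d, t(box))
  sqrt(colSums(d^2))
}

# Resolve one point per subunit for a selection-like expression: an atom if
# the per-subunit match is a single atom, otherwise the mass-weighted COM.
# Returns a list of 3 x n_frames matrices, one per subunit, in config order.
subunit_points <- function(frames, topology, expression,
                           config = channel_config()) {
  pts <- lapply(config$subunits, function(s) {
    sel <- suppressWarnings(
      select(topology, sprintf("(%s) and subunit %s", expression, s)))
    if (length(sel$indices) == 0L)
      stop(sprintf("no atoms for '%s' in subunit %s", expression, s))
    if (length(sel$indices) == 1L) atom_track(frames, sel$indices)
    else com_track(frames, topology, sel$indices)
  })
  names(pts) <- config$subunits
  pts
}

# Pore axis as the unweighted xy centre of the filter C-alpha atoms,
# per frame: 2 x n_frames matrix.
pore_axis <- function(frames, topology, config = channel_config()) {
  sel <- suppressWarnings(select(topology, sprintf("resid %d:%d and name CA",
                                                   config$filter_resids[1],
                                                   config$filter_resids[2])))
  if (length(sel$indices) == 0L) stop("cannot define pore axis: no filter CA atoms")
  sub <- frames$coords[sel$indices + 1L, 1:2, , drop = FALSE]
  apply(sub, c(2L, 3L), mean)
}

# Mean z of a selection per frame (vector length n_frames).
plane_z <- function(frames, topology, expression) {
  sel <- suppressWarnings(select(topology, expression))
  if (length(sel$indices) == 0L) stop("empty selection for plane: ", expression)
  sub <- frames$coords[sel$indices + 1L, 3L, , drop = FALSE]
  apply(sub, 3L, mean)
}
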