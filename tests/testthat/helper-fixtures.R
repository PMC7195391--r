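# Fixture builders shared across the suite. Everything is generated in
# code; no binary files.

# Minimal topology from a bare atom table (internal constructor).
mini_topology <- function(atom_name, residue_name, residue_id, subunit,
                          element = NULL) {
  element <- element %||% kinkgate::infer_element(atom_name)
  atoms <- data.frame(atom_id = seq_along(atom_name) - 1L,
                      atom_name = atom_name, residue_name = residue_name,
                      residue_id = as.integer(residue_id), subunit = subunit,
                      element = element,
                      vdw_radius = unname(
                        ifelse(is.na(kinkgate::default_radius_table()[toupper(element)]),
                               0.17,
                               kinkgate::default_radius_table()[toupper(element)])),
                      stringsAsFactors = FALSE)
  kinkgate:::new_topology(atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One point-atom per subunit (resid/name configurable), with coordinates
# supplied per frame as a list of 4 x 3 matrices.
ring_fixture <- function(xyz_per_frame, resid = 19L, name = "CA",
                         resname = "PRO", box = c(10, 10, 10)) {
  top <- mini_topology(rep(name, 4L), rep(resname, 4L), rep(resid, 4L),
                       c("A", "B", "C", "D"))
  if (is.matrix(xyz_per_frame)) xyz_per_frame <- list(xyz_per_frame)
  coords <- array(NA_real_, c(4L, 3L, length(xyz_per_frame)))
  for (f in seq_along(xyz_per_frame)) coords[, , f] <- xyz_per_frame[[f]]
  list(topology = top, frames = kinkgate::frame_series(coords, box))
}

# Four points at the corners of a square of given side, centred at c0.
square_points <- function(side, z = 0, c0 = c(5, 5)) {
  h <- side / 2
  rbind(c(c0[1] - h, c0[2] - h, z), c(c0[1] + h, c0[2] - h, z),
        c(c0[1] + h, c0[2] + h, z), c(c0[1] - h, c0[2] + h, z))
}

# Brute-force permeation oracle: collapse consecutive duplicate
# compartments and count -1,0,+1 (outward) and +1,0,-1 (inward) patterns.
oracle_count_events <- function(comp) {
  comp <- comp[c(TRUE, diff(comp) != 0)]
  plus <- 0L; minus <- 0L
  if (length(comp) >= 3L) {
    for (i in seq_len(length(comp) - 2L)) {
      tri <- comp[i:(i + 2L)]
      if (identical(tri, c(-1L, 0L, 1L))) plus <- plus + 1L
      if (identical(tri, c(1L, 0L, -1L))) minus <- minus + 1L
    }
  }
  c(plus = plus, minus = minus)
}

# Compartment labels for a z series and fixed bounds.
compartments <- function(z, z_low, z_high) {
  ifelse(z < z_low, -1L, ifelse(z > z_high, 1L, 0L))
}

# A random 3-D rotation matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid motion to all frames of a frame_series.
transform_frames <- function(frames, R = diag(3), shift = c(0, 0, 0)) {
  out <- frames$coords
  for (f in seq_len(dim(out)[3]))
    out[, , f] <- sweep(out[, , f] %*% t(R), 2L, shift, "+")
  kinkgate::frame_series(out, frames$box, frames$times)
}

# Small, fast generator spec for pipeline-level tests.
quick_spec <- function(n_frames = 300L, seed = 11L, ...) {
  kinkgate::synthetic_spec(n_frames = n_frames, seed = seed, ...)
}
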