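#' Construct a frame series
#'
#' The in-memory trajectory container: a `n_atoms x 3 x n_frames` coordinate
#' array in nm, per-frame orthorhombic box dimensions in nm, and strictly
#' increasing times in ns.
#'
#' @param coords numeric array `c(n_atoms, 3, n_frames)` (nm); a single
#'   `n_atoms x 3` matrix is promoted to one frame
#' @param box per-frame box: length-3 vector (recycled) or `n_frames x 3`
#'   matrix (nm)
#' @param times per-frame times in ns, or NULL to use `(0:(n-1)) * dt`
#' @param dt frame spacing (ns) used when `times` is NULL
#' @return object of class `frame_series`
#' @export
frame_series <- function(coords, box, times = NULL, dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(box) == nf, ncol(box) == 3L)
  if (any(box[, 3] <= 0)) stop("box z-dimension must be > 0 in every frame")
  times <- times %||% ((seq_len(nf) - 1) * dt)
  stopifnot(length(times) == nf)
  if (any(times < 0)) stop("times must be non-negative")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(coords = coords, box = box, times = as.numeric(times)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d atoms x %d frames, t = %.4g..%.4g ns, box z %.3g nm\n",
              dim(x$coords)[1], dim(x$coords)[3],
              x$times[1], x$times[length(x$times)], x$box[1, 3]))
  invisible(x)
}

#' @rdname frame_series
#' @param frames a `frame_series`
#' @export
n_frames <- function(frames) dim(frames$coords)[3]

#' @rdname frame_series
#' @export
n_atoms_frames <- function(frames) dim(frames$coords)[1]

#' Subset frames of a frame series
#' @param frames a `frame_series`
#' @param idx frame indices (1-based)
#' @return a `frame_series`
#' @export
subset_frames <- function(frames, idx) {
  frame_series(frames$coords[, , idx, drop = FALSE],
               frames$box[idx, , drop = FALSE], frames$times[idx])
}

#' Read a trajectory into a frame series
#'
#' Supported formats: DCD (binary, coordinates in Angstrom on disk,
#' converted to nm) and multi-model PDB. Truncated DCD files yield a
#' warning and the frames read up to the last intact one. Only orthorhombic
#' boxes are supported; triclinic cells raise an error.
#'
#' @param path trajectory file
#' @param topology matching [topology] (atom counts are checked)
#' @param stride keep every `stride`-th frame
#' @param dt frame spacing in ns assigned to the frames read (trajectory
#'   formats do not carry reliable time stamps); times of strided frames
#'   are preserved on the original grid
#' @param format "dcd", "pdb" or NULL to guess from the extension
#' @param box fallback length-3 box (nm) for files without cell records
#' @return a `frame_series`
#' @export
read_frames <- function(path, topology, stride = 1L, dt = 1, format = NULL,
                        box = NULL) {
  stopifnot(inherits(topology, "topology"), stride >= 1L)
  format <- format %||% tolower(tools::file_ext(path))
  out <- switch(format,
                dcd = read_dcd_frames(path),
                pdb = read_pdb_frames(path),
                stop("unsupported trajectory format: ", format))
  if (dim(out$coords)[1] != topology$n_atoms)
    stop(sprintf("topology mismatch: trajectory has %d atoms, topology %d",
                 dim(out$coords)[1], topology$n_atoms))
  if (is.null(out$box)) {
    if (is.null(box)) stop("trajectory carries no box; supply `box`")
    out$box <- matrix(box, nrow = dim(out$coords)[3], ncol = 3L, byrow = TRUE)
  }
  nf <- dim(out$coords)[3]
  keep <- seq(1L, nf, by = stride)
  frame_series(out$coords[, , keep, drop = FALSE],
               out$box[keep, , drop = FALSE],
               times = (keep - 1L) * dt)
}

# Multi-model PDB via bio3d; the box comes from the first CRYST1 record.
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  na <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  box <- NULL
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl) > 0L) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
    ang <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                        substr(cl[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3))
      stop("triclinic boxes are not supported (CRYST1 angles != 90)")
    box <- matrix(v / 10, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  list(coords = coords, box = box)
}

# Minimal CHARMM-style DCD reader. bio3d::read.dcd serves as the
# independent cross-check in the tests; this reader exists so truncated
# files stop cleanly at the last intact frame and cell handling stays in
# one place.
read_dcd_frames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  end <- .Platform$endian
  marker <- readBin(con, "integer", 1L, endian = end)
  if (!identical(marker, 84L)) stop("not a DCD file (bad header record)")
  hdr <- readChar(con, 4L)
  if (!identical(hdr, "CORD")) stop("not a coordinate DCD file")
  icntrl <- readBin(con, "integer", 20L, endian = end)
  nframe <- icntrl[1]; cryst <- icntrl[11]; vers <- icntrl[20]
  readBin(con, "integer", 1L, endian = end)
  m <- readBin(con, "integer", 1L, endian = end)
  ntitle <- readBin(con, "integer", 1L, endian = end)
  if (ntitle > 0L) readChar(con, 80L * ntitle, useBytes = TRUE)
  readBin(con, "integer", 1L, endian = end)
  readBin(con, "integer", 1L, endian = end)
  natom <- readBin(con, "integer", 1L, endian = end)
  readBin(con, "integer", 1L, endian = end)
  has_cell <- vers != 0L && cryst == 1L
  coords <- array(NA_real_, c(natom, 3L, nframe))
  box <- if (has_cell) matrix(NA_real_, nframe, 3L) else NULL
  got <- 0L
  for (f in seq_len(nframe)) {
    frame <- tryCatch({
      cell <- NULL
      if (has_cell) {
        a <- readBin(con, "integer", 1L, endian = end)
        u <- readBin(con, "double", 6L, endian = end)
        readBin(con, "integer", 1L, endian = end)
        if (length(u) < 6L) stop("truncated")
        cell <- u
      }
      xyz <- matrix(NA_real_, natom, 3L)
      for (d in 1:3) {
        a <- readBin(con, "integer", 1L, endian = end)
        v <- readBin(con, "double", natom, size = 4L, endian = end)
        readBin(con, "integer", 1L, endian = end)
        if (length(v) < natom) stop("truncated")
        xyz[, d] <- v
      }
      list(cell = cell, xyz = xyz)
    }, error = function(e) NULL)
    if (is.null(frame)) break
    coords[, , f] <- frame$xyz / 10
    if (has_cell) {
      # CHARMM cell record: a, cos(gamma), b, cos(beta), cos(alpha), c
      if (any(abs(frame$cell[c(2, 4, 5)]) > 1e-6))
        stop("triclinic boxes are not supported")
      box[f, ] <- frame$cell[c(1, 3, 6)] / 10
    }
    got <- f
  }
  if (got < nframe) {
    warning(sprintf("truncated DCD: read %d of %d frames", got, nframe))
    coords <- coords[, , seq_len(got), drop = FALSE]
    if (has_cell) box <- box[seq_len(got), , drop = FALSE]
  }
  if (got == 0L) stop("no intact frames in ", path)
  list(coords = coords, box = box)
}

#' Write a frame series to disk
#'
#' Multi-model PDB (text; 0.001 Angstrom coordinate precision) or binary
#' CHARMM-style DCD with per-frame cell records (float32, about 1e-5 nm
#' precision at typical box sizes).
#'
#' @param frames a `frame_series`
#' @param topology the matching [topology]
#' @param path output file
#' @param format "pdb" or "dcd"; guessed from the extension when NULL
#' @return `path`, invisibly
#' @export
write_frames <- function(frames, topology, path, format = NULL) {
  stopifnot(inherits(frames, "frame_series"), inherits(topology, "topology"))
  if (n_atoms_frames(frames) != topology$n_atoms)
    stop("topology mismatch between frames and topology")
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         pdb = write_pdb_frames(frames, topology, path),
         dcd = write_dcd_frames(frames, path),
         stop("unsupported trajectory format: ", format))
  invisible(path)
}

pdb_atom_lines <- function(xyz_ang, atoms) {
  name4 <- ifelse(nchar(atoms$atom_name) < 4L,
                  sprintf(" %-3s", atoms$atom_name),
                  atoms$atom_name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (atoms$atom_id %% 99999L) + 1L, name4,
          substr(atoms$residue_name, 1L, 3L),
          substr(atoms$subunit, 1L, 1L),
          atoms$residue_id %% 10000L,
          xyz_ang[, 1], xyz_ang[, 2], xyz_ang[, 3], 1, 0,
          substr(atoms$element, 1L, 2L))
}

write_pdb_frames <- function(frames, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- frames$box[1, ] * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  for (f in seq_len(n_frames(frames))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(pdb_atom_lines(frames$coords[, , f] * 10, topology$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_dcd_frames <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  na <- n_atoms_frames(frames)
  nf <- n_frames(frames)
  icntrl <- integer(20L)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L; icntrl[20] <- 24L
  writeBin(84L, con)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(icntrl, con)
  writeBin(84L, con)
  title <- formatC("written by kinkgate", width = -80L)
  writeBin(84L, con); writeBin(1L, con)
  writeChar(title, con, nchars = 80L, eos = NULL)
  writeBin(84L, con)
  writeBin(4L, con); writeBin(as.integer(na), con); writeBin(4L, con)
  for (f in seq_len(nf)) {
    b <- frames$box[f, ] * 10
    writeBin(48L, con)
    writeBin(c(b[1], 0, b[2], 0, 0, b[3]), con, size = 8L)
    writeBin(48L, con)
    xyz <- frames$coords[, , f] * 10
    for (d in 1:3) {
      writeBin(as.integer(4L * na), con)
      writeBin(as.numeric(xyz[, d]), con, size = 4L)
      writeBin(as.integer(4L * na), con)
    }
  }
}

#' Unwrap a periodic z-series
#'
#' Removes periodic-boundary jumps from a per-frame z coordinate series:
#' any step of at least half a box length is shifted by the appropriate
#' integer number of box lengths, so ion tracks become continuous. The
#' first value is returned unchanged.
#'
#' @param z numeric vector of wrapped z values (nm)
#' @param box_z box z-dimension, scalar or per-frame vector (nm)
#' @return continuous z series of the same length
#' @examples
#' unwrap_z(c(4.4, 4.6, -4.5), 9.2)  # -> 4.4 4.6 4.7
#' @export
unwrap_z <- function(z, box_z) {
  stop_if_not_finite(z, "z")
  stop_if_not_finite(box_z, "box_z")
  n <- length(z)
  if (n <= 1L) return(z)
  bz <- if (length(box_z) == 1L) rep(box_z, n) else box_z
  stopifnot(length(bz) == n, all(bz > 0))
  dz <- diff(z)
  b <- bz[-1L]
  dz <- dz - b * round(dz / b)
  z[1L] + c(0, cumsum(dz))
}

#' Wrap z values into the primary box [0, box_z)
#' @param z numeric vector (nm)
#' @param box_z box z-dimension (nm), scalar or per-element
#' @return wrapped values
#' @export
wrap_z <- function(z, box_z) z - floor(z / box_z) * box_z
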