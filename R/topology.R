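#' Default van der Waals radius table (nm)
#'
#' Bondi-style radii used to assign a radius to every atom at load time;
#' the pore-radius profile subtracts these from axis distances.
#'
#' @return named numeric vector, element symbol -> radius in nm
#' @export
default_radius_table <- function() {
  c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
    K = 0.275, F = 0.147, CL = 0.175, `NA` = 0.227, MG = 0.173)
}

#' Infer element symbols from atom names
#'
#' PDB files without an element column get elements from the atom name:
#' leading digits and primes are stripped and the first character is taken,
#' except for a small set of full-name matches (K, NA, CL, MG, P as ions).
#'
#' @param atom_name character vector of atom names
#' @return character vector of element symbols
#' @export
infer_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", toupper(trimws(atom_name)))
  full <- c("K", "NA", "CL", "MG", "OW", "HW")
  out <- substr(nm, 1L, 1L)
  out[nm == "K"] <- "K"
  out[nm == "NA"] <- "NA"
  out[nm == "CL"] <- "CL"
  out[nm == "MG"] <- "MG"
  out[nm == "OW"] <- "O"
  out
}

new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_id", "atom_name", "residue_name", "residue_id",
            "subunit", "element", "vdw_radius")
  if (!all(need %in% names(atoms)))
    stop("atom table misses columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty topology: zero atoms")
  if (anyDuplicated(atoms$atom_id) || !identical(sort(atoms$atom_id),
                                                 seq_len(nrow(atoms)) - 1L))
    stop("atom_id must be unique and contiguous from 0")
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop("every atom needs a vdw_radius > 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms)), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, subunits: %s\n",
              x$n_atoms, length(unique(paste(x$atoms$subunit, x$atoms$residue_id))),
              paste(unique(x$atoms$subunit), collapse = " ")))
  invisible(x)
}

# Assign subunit labels where chain ids are absent: atoms are split into
# blocks wherever the residue numbering restarts (decreases), and blocks are
# labelled A, B, C, ... in file order.
infer_subunits <- function(residue_id) {
  breaks <- c(0L, which(diff(residue_id) < 0L)) + 1L
  block <- findInterval(seq_along(residue_id), breaks)
  lab <- rep(LETTERS, length.out = max(block))
  lab[block]
}

assign_radii <- function(element, radius_table, default_radius) {
  r <- radius_table[toupper(element)]
  r[is.na(r)] <- default_radius
  unname(r)
}

#' Load a topology from a PDB or GRO file
#'
#' Atom names, residues and subunit (chain) labels are read and every atom
#' is assigned a van der Waals radius from an element table. When the file
#' carries no element column, elements are inferred from atom names; when it
#' carries no chain labels, subunits are inferred from residue-numbering
#' restarts. Backbone amide hydrogens named `H` (PDB v3) are normalized to
#' the internal alias `HN` (CHARMM) so selections resolve either way.
#'
#' @param path PDB or GRO file
#' @param radius_table named element -> nm radius map
#' @param default_radius radius (nm) for elements missing from the table
#' @param format "pdb", "gro", or NULL to guess from the extension
#' @return a `topology` object; coordinates are not retained (use
#'   [read_frames()] for coordinates)
#' @export
load_topology <- function(path, radius_table = default_radius_table(),
                          default_radius = 0.17, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (!nzchar(format)) stop("cannot guess topology format for ", path)
  atoms <- switch(format,
                  pdb = parse_pdb_atoms(path),
                  gro = parse_gro_atoms(path),
                  stop("unsupported topology format: ", format))
  if (nrow(atoms) == 0L) stop("empty input: no atoms in ", path)
  atoms$atom_name[atoms$atom_name == "H"] <- "HN"
  if (all(is.na(atoms$subunit) | atoms$subunit == ""))
    atoms$subunit <- infer_subunits(atoms$residue_id)
  atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                          infer_element(atoms$atom_name), atoms$element)
  atoms$vdw_radius <- assign_radii(atoms$element, radius_table, default_radius)
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  new_topology(atoms[, c("atom_id", "atom_name", "residue_name",
                         "residue_id", "subunit", "element", "vdw_radius")])
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty input: no atoms in ", path)
  data.frame(atom_id = seq_len(nrow(a)) - 1L,
             atom_name = trimws(a$elety),
             residue_name = trimws(a$resid),
             residue_id = as.integer(a$resno),
             subunit = ifelse(is.na(a$chain), "", a$chain),
             element = if ("elesy" %in% names(a)) trimws(a$elesy) else "",
             vdw_radius = NA_real_,
             stringsAsFactors = FALSE)
}

# GROMACS .gro: title, atom count, fixed-width atom records (positions in
# nm), box line. No chain column; subunits come from residue restarts.
parse_gro_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("unparseable or empty GRO file ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 1L) stop("empty input: no atoms in ", path)
  if (length(lines) < 2L + n) stop("truncated GRO file ", path)
  rec <- lines[3:(2L + n)]
  data.frame(atom_id = seq_len(n) - 1L,
             atom_name = trimws(substr(rec, 11L, 15L)),
             residue_name = trimws(substr(rec, 6L, 10L)),
             residue_id = as.integer(substr(rec, 1L, 5L)),
             subunit = "",
             element = "",
             vdw_radius = NA_real_,
             stringsAsFactors = FALSE)
}
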