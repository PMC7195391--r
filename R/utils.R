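`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed, restoring global state afterwards
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (any(!is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

#' Standard error of the mean
#' @param x numeric vector
#' @return sd(x)/sqrt(n); NA for a single value (never reported as 0)
#' @keywords internal
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Channel geometry configuration
#'
#' Residue-level description of the tetrameric pore domain used by all
#' descriptor functions. Defaults follow the MthK pore domain: selectivity
#' filter TVGYG at residues 59-63, inner helix 71-98 with the hinge glycine
#' at 83, outer helix ending at Pro19.
#'
#' @param subunits four subunit labels, in the order in which opposite
#'   (diagonal) pairs are formed as (1,3) and (2,4)
#' @param filter_resids residue interval of the selectivity filter
#' @param inner_helix residue interval of the pore-lining inner helix
#' @param hinge residue id of the hinge glycine
#' @param outer_helix residue interval of the outer helix
#' @param kink_pairs backbone hydrogen bonds broken in the kinked state,
#'   as a list of c(acceptor_resid, donor_resid) pairs (O of the first,
#'   amide H of the second)
#' @param thr59,gly61,ile84,phe87,pro19 residue ids of the named gating
#'   residues (renameable for homologues)
#' @param ion_resname,water_resname,phosphate_name selections for K+ ions,
#'   water oxygens and lipid phosphates
#' @return a list of class `channel_config`
#' @export
channel_config <- function(subunits = c("A", "B", "C", "D"),
                           filter_resids = c(59L, 63L),
                           inner_helix = c(71L, 98L),
                           hinge = 83L,
                           outer_helix = c(12L, 19L),
                           kink_pairs = list(VG = c(81L, 85L), LT = c(82L, 86L)),
                           thr59 = 59L, gly61 = 61L, ile84 = 84L,
                           phe87 = 87L, pro19 = 19L,
                           ion_resname = "K", water_resname = "SOL",
                           phosphate_name = "P") {
  stopifnot(length(subunits) == 4L)
  structure(list(subunits = subunits, filter_resids = filter_resids,
                 inner_helix = inner_helix, hinge = hinge,
                 outer_helix = outer_helix, kink_pairs = kink_pairs,
                 thr59 = thr59, gly61 = gly61, ile84 = ile84,
                 phe87 = phe87, pro19 = pro19,
                 ion_resname = ion_resname, water_resname = water_resname,
                 phosphate_name = phosphate_name),
            class = "channel_config")
}

#' Atomic masses (u) by element
#' @param element character vector of element symbols
#' @return numeric masses; unknown elements fall back to carbon
#' @keywords internal
element_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, K = 39.098, F = 18.998, NA. = 22.99, CL = 35.45,
           MG = 24.305)
  names(tab)[names(tab) == "NA."] <- "NA"
  m <- tab[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}
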