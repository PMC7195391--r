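#' Backbone hydrogen-bond distance per subunit
#'
#' Distance between a backbone carbonyl oxygen and a backbone amide
#' hydrogen within each subunit, the discriminator of the kinked state
#' (broken Val81 O - Gly85 HN bond) versus the bent state (bond formed).
#' Minimum-image convention is applied.
#'
#' For heavy-atom-only topologies there is no amide hydrogen; set
#' `use_heavy = TRUE` to fall back to the O-N distance (classification
#' thresholds should then be shifted by +0.1 nm, see [classify_state()]).
#'
#' @param frames a [frame_series]
#' @param topology the matching [topology]
#' @param acceptor_resid residue carrying the backbone O (default Val81)
#' @param donor_resid residue carrying the backbone amide H (default Gly85)
#' @param use_heavy use the donor backbone N instead of the amide H
#' @param config a [channel_config()]
#' @return `n_frames x 4` matrix of distances (nm), columns named by subunit
#' @export
hbond_distance <- function(frames, topology, acceptor_resid = 81L,
                           donor_resid = 85L, use_heavy = FALSE,
                           config = channel_config()) {
  donor_name <- if (use_heavy) "N" else "HN"
  out <- sapply(config$subunits, function(s) {
    acc <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d and name O", s, acceptor_resid)))
    don <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d and name %s", s, donor_resid, donor_name)))
    if (length(acc$indices) != 1L)
      stop(sprintf("need exactly one backbone O for resid %d subunit %s",
                   acceptor_resid, s))
    if (length(don$indices) != 1L)
      stop(sprintf(paste0("no amide hydrogen (name HN or H) for resid %d ",
                          "subunit %s; supply hydrogens or set use_heavy = ",
                          "TRUE for the O-N fallback (shift thresholds ",
                          "+0.1 nm)"), donor_resid, s))
    pair_distance(frames, acc$indices, don$indices)
  })
  matrix(out, ncol = 4L, dimnames = list(NULL, config$subunits))
}

# First principal axis of a point set, oriented along `orient` (a vector
# whose dot product with the axis is made positive).
principal_axis <- function(pts, orient) {
  c0 <- sweep(pts, 2L, colMeans(pts))
  v <- svd(c0, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(v * orient) < 0) v <- -v
  v
}

#' Inner-helix bending angle per subunit
#'
#' Angle between the principal axes of the C-alpha atoms on the two sides
#' of the hinge residue (the flanking segments `[start, hinge-1]` and
#' `[hinge+1, end]`), each axis oriented N-terminal to C-terminal. 0 deg
#' means a straight helix; the kinked and bent states sit near 43 and 30
#' deg respectively.
#'
#' @inheritParams hbond_distance
#' @param helix_range length-2 residue interval of the helix (default from
#'   `config`)
#' @param hinge hinge residue id (default from `config`)
#' @return `n_frames x 4` matrix of angles (degrees); a subunit with fewer
#'   than 4 C-alpha atoms on either side is all-NA
#' @export
bending_angle <- function(frames, topology, helix_range = NULL, hinge = NULL,
                          config = channel_config()) {
  helix_range <- helix_range %||% config$inner_helix
  hinge <- hinge %||% config$hinge
  nf <- n_frames(frames)
  out <- matrix(NA_real_, nf, 4L, dimnames = list(NULL, config$subunits))
  for (s in config$subunits) {
    ca <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d:%d and name CA",
              s, helix_range[1], helix_range[2])))
    resid <- topology$atoms$residue_id[ca$indices + 1L]
    ord <- order(resid)
    idx <- ca$indices[ord] + 1L
    resid <- resid[ord]
    upper <- idx[resid < hinge]
    lower <- idx[resid > hinge]
    if (length(upper) < 4L || length(lower) < 4L) next
    for (f in seq_len(nf)) {
      pu <- frames$coords[upper, , f]
      pl <- frames$coords[lower, , f]
      # orient both axes N -> C (first to last residue of the segment)
      au <- principal_axis(pu, pu[nrow(pu), ] - pu[1L, ])
      al <- principal_axis(pl, pl[nrow(pl), ] - pl[1L, ])
      out[f, s] <- acos(max(-1, min(1, sum(au * al)))) * 180 / pi
    }
  }
  out
}

#' Classify subunits as kinked or bent per frame
#'
#' Two-threshold hysteresis classifier on the Val81 O - Gly85 HN distance:
#' a subunit is labelled bent when the distance drops below `t_low` and
#' kinked when it rises above `t_high`; inside the band the previous label
#' is kept (label flicker at the barrier is suppressed). The first frame
#' takes the nearer threshold, ties going to kinked. With
#' `hysteresis = FALSE` a single cutoff at the band midpoint is used.
#'
#' @param d_vg `n_frames x n_subunits` matrix of Val81 O - Gly85 HN
#'   distances (nm), e.g. from [hbond_distance()]
#' @param t_low bent threshold (nm)
#' @param t_high kinked threshold (nm)
#' @param hysteresis use the two-threshold rule (default) or a single cutoff
#' @return object of class `state_trace`: per-frame per-subunit `labels`
#'   ("kinked"/"bent"), overall bent-state fraction `f_bent`, per-subunit
#'   fractions, and the per-frame count of bent subunits `n_bent`
#' @examples
#' d <- cbind(A = rep(0.2, 10), B = rep(0.55, 10),
#'            C = rep(0.55, 10), D = rep(0.55, 10))
#' classify_state(d)$f_bent  # 0.25: one permanently bent subunit
#' @export
classify_state <- function(d_vg, t_low = 0.27, t_high = 0.45,
                           hysteresis = TRUE) {
  d_vg <- as.matrix(d_vg)
  stop_if_not_finite(d_vg, "d_vg")
  stopifnot(t_low < t_high)
  nf <- nrow(d_vg)
  labels <- matrix(NA_character_, nf, ncol(d_vg),
                   dimnames = dimnames(d_vg))
  for (s in seq_len(ncol(d_vg))) {
    d <- d_vg[, s]
    if (!hysteresis) {
      labels[, s] <- ifelse(d < (t_low + t_high) / 2, "bent", "kinked")
      next
    }
    lab <- character(nf)
    # first frame: nearer threshold wins, tie -> kinked
    lab[1L] <- if (abs(d[1L] - t_low) < abs(d[1L] - t_high)) "bent" else "kinked"
    if (d[1L] < t_low) lab[1L] <- "bent"
    if (d[1L] > t_high) lab[1L] <- "kinked"
    for (f in seq_len(nf)[-1L]) {
      lab[f] <- if (d[f] < t_low) "bent"
        else if (d[f] > t_high) "kinked"
        else lab[f - 1L]
    }
    labels[, s] <- lab
  }
  new_state_trace(labels)
}

new_state_trace <- function(labels) {
  bent <- labels == "bent"
  structure(list(labels = labels,
                 f_bent = mean(bent),
                 f_bent_by_subunit = colMeans(bent),
                 n_bent = as.integer(rowSums(bent)),
                 n_frames = nrow(labels)),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d frames x %d subunits, f_bent = %.3f\n",
              x$n_frames, ncol(x$labels), x$f_bent))
  invisible(x)
}

#' Cross-subunit ring distance
#'
#' Distance characterizing the opening of a ring of four equivalent points
#' (one atom or side-chain COM per subunit), e.g. the Thr59 O-gamma ring of
#' the filter entrance or the Pro19 C-alpha ring of the outer helices.
#' Diagonal pairing (default) averages the two opposite-subunit distances
#' (A-C and B-D); all-pairs averages all six.
#'
#' @inheritParams hbond_distance
#' @param expression selection resolving exactly one point per subunit
#'   (several atoms per subunit are reduced to their mass-weighted COM)
#' @param pairing "diagonal" or "all"
#' @return numeric vector, one distance (nm) per frame
#' @export
cross_subunit_distance <- function(frames, topology, expression,
                                   pairing = c("diagonal", "all"),
                                   config = channel_config()) {
  pairing <- match.arg(pairing)
  pts <- subunit_points(frames, topology, expression, config)
  if (length(pts) != 4L) stop("tetramer-shape error: need 4 subunit points")
  ring_distance(pts, pairing)
}

ring_distance <- function(pts, pairing = "diagonal") {
  if (pairing == "diagonal") {
    (point_distance(pts[[1]], pts[[3]]) +
       point_distance(pts[[2]], pts[[4]])) / 2
  } else {
    pairs <- utils::combn(4L, 2L)
    d <- 0
    for (k in seq_len(ncol(pairs)))
      d <- d + point_distance(pts[[pairs[1, k]]], pts[[pairs[2, k]]])
    d / ncol(pairs)
  }
}

#' Intra-subunit side-chain COM distance
#'
#' Distance between the mass-weighted side-chain heavy-atom COMs (C-beta
#' included, hydrogens excluded) of two residues within each subunit; the
#' default pair Ile84-Thr59 couples the inner-helix kink to the filter
#' entrance.
#'
#' @inheritParams hbond_distance
#' @param res_a,res_b residue ids
#' @return `n_frames x 4` matrix (nm), plus the per-frame subunit mean as
#'   attribute `"system"`
#' @export
sidechain_com_distance <- function(frames, topology, res_a = 84L, res_b = 59L,
                                   config = channel_config()) {
  out <- sapply(config$subunits, function(s) {
    ga <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d and sidechain", s, res_a)))
    gb <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d and sidechain", s, res_b)))
    if (length(ga$indices) == 0L)
      stop(sprintf("residue %d has no side-chain heavy atoms (glycine?)", res_a))
    if (length(gb$indices) == 0L)
      stop(sprintf("residue %d has no side-chain heavy atoms (glycine?)", res_b))
    point_distance(com_track(frames, topology, ga$indices),
                   com_track(frames, topology, gb$indices))
  })
  out <- matrix(out, ncol = 4L, dimnames = list(NULL, config$subunits))
  attr(out, "system") <- rowMeans(out)
  out
}

#' Ring distance of side-chain COMs of one residue
#'
#' Mean of the two diagonal distances between the four per-subunit
#' side-chain COMs of a residue (default Ile84); e.g. four COMs on a circle
#' of radius r give 2r.
#'
#' @inheritParams hbond_distance
#' @param res residue id
#' @return numeric vector, one distance (nm) per frame
#' @export
com_ring_distance <- function(frames, topology, res = 84L,
                              config = channel_config()) {
  cross_subunit_distance(frames, topology,
                         sprintf("resid %d and sidechain", res),
                         pairing = "diagonal", config = config)
}

#' Phe87-CoF distance per subunit
#'
#' Distance between each subunit's Phe87 side-chain COM and the COM of the
#' four Phe87 C-alpha atoms (the "CoF"). Small values mean the side chain
#' points into the central cavity (bent state, dehydrated cavity); large
#' values mean it points between subunits (kinked state, hydrated cavity).
#'
#' @inheritParams hbond_distance
#' @param res residue id of the cavity-lining phenylalanine
#' @return `n_frames x 4` matrix (nm)
#' @export
phe87_cof_distance <- function(frames, topology, res = 87L,
                               config = channel_config()) {
  ca <- suppressWarnings(select(topology, sprintf("resid %d and name CA", res)))
  if (length(ca$indices) != 4L)
    stop(sprintf("need the 4 C-alpha atoms of resid %d (found %d)",
                 res, length(ca$indices)))
  cof <- apply(frames$coords[ca$indices + 1L, , , drop = FALSE], c(2L, 3L), mean)
  out <- sapply(config$subunits, function(s) {
    sc <- suppressWarnings(select(topology,
      sprintf("subunit %s and resid %d and sidechain", s, res)))
    if (length(sc$indices) == 0L)
      stop(sprintf("no side-chain atoms for resid %d subunit %s", res, s))
    point_distance(com_track(frames, topology, sc$indices), cof)
  })
  matrix(out, ncol = 4L, dimnames = list(NULL, config$subunits))
}

#' Two-dimensional histogram
#'
#' Joint histogram of two descriptor series (e.g. bending angle vs the
#' Val81 O - Gly85 HN distance); pairs with a non-finite member are dropped.
#'
#' @param x,y numeric vectors of equal length
#' @param xbreaks,ybreaks bin edges (finite, increasing)
#' @param normalize return probabilities (grid sums to 1) instead of counts
#' @return list with `x_mid`, `y_mid` bin centres and the count (or
#'   probability) matrix `z` (`length(x_mid)` rows)
#' @export
histogram2d <- function(x, y, xbreaks, ybreaks, normalize = FALSE) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  stop_if_not_finite(xbreaks, "xbreaks")
  stop_if_not_finite(ybreaks, "ybreaks")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ix <- findInterval(x, xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(y, ybreaks, rightmost.closed = TRUE)
  keep <- ix >= 1L & ix < length(xbreaks) & iy >= 1L & iy < length(ybreaks)
  z <- matrix(0, length(xbreaks) - 1L, length(ybreaks) - 1L)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_len(nrow(z))),
                 factor(iy[keep], levels = seq_len(ncol(z))))
    z <- matrix(as.numeric(tab), nrow(z), ncol(z))
  }
  if (normalize && sum(z) > 0) z <- z / sum(z)
  list(x_mid = (xbreaks[-1L] + head(xbreaks, -1L)) / 2,
       y_mid = (ybreaks[-1L] + head(ybreaks, -1L)) / 2,
       z = z)
}
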