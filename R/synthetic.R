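# Synthetic trajectory generator. The geometry is schematic -- helices are
# parametrized C-alpha traces decorated with the named key atoms -- not a
# physical model: only the descriptors the pipeline measures (kink
# hydrogen-bond distances, bending angles, Thr59 O-gamma ring radius,
# Phe87-CoF distance, Ile84-Thr59 distance, crossing-ion tracks, cavity
# water counts, phosphate layers) are planted faithfully, each with full
# ground truth, so recovery of every planted quantity is testable.

#' Specification of a synthetic channel trajectory
#'
#' Defines the statistical structure planted in a generated trajectory:
#' per-subunit two-state Markov gating between kinked and bent templates,
#' gate geometry coupled to the number of bent subunits, and
#' configuration-dependent Poisson ion crossings under an applied field.
#'
#' @param n_frames number of frames
#' @param dt frame spacing (ns)
#' @param seed integer seed; fully determines the output
#' @param k_kb,k_bk kinked-to-bent and bent-to-kinked rates (1/ns); the
#'   stationary bent fraction is `k_kb / (k_kb + k_bk)`
#' @param templates kinked/bent geometry parameters: `d_vg`, `d_lt` (nm,
#'   backbone H-bond distances), `angle` (deg), `d_cof`, `d_i84t59` (nm)
#'   each as c(kinked=, bent=); `og_diag` (nm) as a length-5 vector of the
#'   Thr59 O-gamma diagonal distance for 0..4 bent subunits
#' @param noise_sigma isotropic Gaussian positional noise on protein atoms
#'   (nm)
#' @param lambda_by_config outward crossing rate (events/us) for 0..4 bent
#'   subunits; the planted two-gate crosstalk makes the rates for the
#'   all-kinked and all-bent configurations lower than the asymmetric ones
#' @param cavity_water_map number of cavity waters for 0..4 bent subunits
#'   (dehydration of the cavity in bent-dominated configurations)
#' @param thickness membrane thickness: phosphate layers sit at
#'   z_center +/- thickness/2 (nm)
#' @param n_ions,n_crossing,n_waters particle counts (`n_crossing` of the
#'   ions form the crossing pool)
#' @param box orthorhombic box (nm); the default z of 9.2308 nm with the
#'   default field of 0.0325 V/nm gives a 300 mV transmembrane voltage
#' @param E_field applied field (V/nm)
#' @param crossing_time_ns duration of one ion traversal
#' @param U optional potential (function of z in nm relative to the Thr59
#'   O-gamma plane, in kBT): switches the generator to equilibrium-ion
#'   mode, with ion z Boltzmann-sampled from exp(-U) and no crossings
#' @param u_z_range z interval sampled in equilibrium-ion mode
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_frames = 2000L, dt = 0.1, seed = 1L,
                           k_kb = 0.015, k_bk = 0.035,
                           templates = list(),
                           noise_sigma = 0.01,
                           lambda_by_config = c(0, 54.7, 54.7, 25, 18),
                           cavity_water_map = c(12L, 12L, 10L, 6L, 2L),
                           thickness = 3.6,
                           n_ions = 16L, n_crossing = 6L, n_waters = 60L,
                           box = c(6.5, 6.5, 9.2308),
                           E_field = 0.0325, crossing_time_ns = 2,
                           U = NULL, u_z_range = c(-1.5, 1.5)) {
  tmpl <- utils::modifyList(list(
    d_vg = c(kinked = 0.55, bent = 0.25),
    d_lt = c(kinked = 0.55, bent = 0.25),
    angle = c(kinked = 43, bent = 30),
    og_diag = c(0.497, 0.512, 0.519, 0.526, 0.533),
    d_cof = c(kinked = 0.836, bent = 0.666),
    d_i84t59 = c(kinked = 0.54, bent = 0.59)), templates)
  if (k_kb < 0 || k_bk < 0) stop("rates must be >= 0")
  if (any(lambda_by_config < 0)) stop("crossing rates must be >= 0")
  stopifnot(length(lambda_by_config) == 5L, length(cavity_water_map) == 5L,
            length(tmpl$og_diag) == 5L, n_crossing <= n_ions,
            n_frames >= 1L, dt > 0, all(box > 0))
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed), k_kb = k_kb, k_bk = k_bk,
                 templates = tmpl, noise_sigma = noise_sigma,
                 lambda_by_config = lambda_by_config,
                 cavity_water_map = as.integer(cavity_water_map),
                 thickness = thickness, n_ions = as.integer(n_ions),
                 n_crossing = as.integer(n_crossing),
                 n_waters = as.integer(n_waters), box = box,
                 E_field = E_field, crossing_time_ns = crossing_time_ns,
                 U = U, u_z_range = u_z_range),
            class = "synthetic_spec")
}

#' Sample per-subunit kinked/bent state sequences
#'
#' Four independent two-state Markov chains sampled on the frame grid with
#' the exact discrete-time transition probabilities of the continuous-time
#' chain; initial states are drawn from the stationary distribution.
#'
#' @param spec a [synthetic_spec()]
#' @param seed seed (default from the spec)
#' @return `n_frames x 4` character matrix of "kinked"/"bent" labels
#' @export
simulate_state_dynamics <- function(spec, seed = spec$seed) {
  a <- spec$k_kb; b <- spec$k_bk
  if (a + b <= 0) stop("k_kb + k_bk must be > 0")
  f_bent <- a / (a + b)
  relax <- 1 - exp(-(a + b) * spec$dt)
  p_kb <- f_bent * relax          # kinked -> bent over one frame
  p_bk <- (1 - f_bent) * relax    # bent -> kinked over one frame
  nf <- spec$n_frames
  with_seed(seed, {
    out <- matrix(NA_character_, nf, 4L,
                  dimnames = list(NULL, c("A", "B", "C", "D")))
    for (s in 1:4) {
      st <- logical(nf)  # TRUE = bent
      st[1L] <- runif(1) < f_bent
      u <- runif(nf - 1L)
      for (f in seq_len(nf - 1L))
        st[f + 1L] <- if (st[f]) u[f] >= p_bk else u[f] < p_kb
      out[, s] <- ifelse(st, "bent", "kinked")
    }
    out
  })
}

# --- schematic geometry ----------------------------------------------------

# Layout constants (absolute z in nm; the box z-centre is at 4.6 for the
# default box). The Thr59 O-gamma plane sits at z = 5.60.
geom_const <- function(spec) {
  list(x0 = spec$box[1] / 2, y0 = spec$box[2] / 2, zc = 4.6,
       z_og = 5.60, z_hinge = 4.20, r_hinge = 1.0, alpha_a = 10,
       rise = 0.15, r_outer = 1.6, r_filter_ca = 0.45, r_filter_o = 0.35,
       r_cb59 = 0.38, z_cb59 = 5.62,
       park_below = 4.0, park_above = 7.6)
}

# Build one subunit's protein atoms for a given state ("kinked"/"bent").
# Returns a data.frame (atom metadata + role) and coordinates in the
# subunit's radial frame mapped to 3-D via the unit vector u = (ux, uy).
subunit_coords <- function(spec, u, state, gc) {
  t <- spec$templates
  theta <- t$angle[[state]]
  rows <- list()
  add <- function(name, resname, resid, element, r, z, role = "static") {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, residue_name = resname, residue_id = resid,
      element = element, x = gc$x0 + r * u[1], y = gc$y0 + r * u[2], z = z,
      role = role, stringsAsFactors = FALSE)
  }
  for (r in 12:19)  # outer helix, Pro19 at its end
    add("CA", if (r == 19L) "PRO" else "ALA", r, "C",
        gc$r_outer, 6.40 - gc$rise * (r - 12L))
  for (r in 54:58)  # pore helix
    add("CA", "ALA", r, "C", 0.9, 5.0 + 0.12 * (r - 54L))
  # selectivity filter TVGYG (59-63): CA + backbone O, Thr59 CB/OG1
  fil <- c(`59` = "THR", `60` = "VAL", `61` = "GLY", `62` = "TYR", `63` = "GLY")
  for (i in seq_along(fil)) {
    r <- 58L + i
    zca <- 5.60 + 0.30 * (i - 1L)
    add("CA", fil[i], r, "C", gc$r_filter_ca, zca)
    if (r == 59L) {
      add("CB", "THR", r, "C", gc$r_cb59, gc$z_cb59)
      add("OG1", "THR", r, "O", NA_real_, gc$z_og, role = "og1")
    }
    add("O", fil[i], r, "O", gc$r_filter_o, zca + 0.15)
  }
  # inner helix 71-98: two straight C-alpha segments meeting at Gly83
  inner_res <- c(`81` = "VAL", `82` = "LEU", `83` = "GLY", `84` = "ILE",
                 `85` = "GLY", `86` = "THR", `87` = "PHE")
  aa <- gc$alpha_a * pi / 180
  ab <- (gc$alpha_a + theta) * pi / 180
  va <- c(sin(aa), -cos(aa))   # (dr, dz), N -> C
  vb <- c(sin(ab), -cos(ab))
  ca81 <- NULL; ca82 <- NULL
  for (r in 71:98) {
    rn <- inner_res[as.character(r)]
    if (is.na(rn)) rn <- "ALA"
    if (r <= 83L) {
      p <- c(gc$r_hinge, gc$z_hinge) - (83L - r) * gc$rise * va
      role <- "static"
    } else {
      p <- c(gc$r_hinge, gc$z_hinge) + (r - 83L) * gc$rise * vb
      role <- "segB"
    }
    add("CA", rn, r, "C", p[1], p[2], role = role)
    if (r == 81L) ca81 <- p
    if (r == 82L) ca82 <- p
  }
  o81 <- ca81 + c(0.15, -0.05)
  o82 <- ca82 + c(0.15, -0.05)
  add("O", "VAL", 81L, "O", o81[1], o81[2])
  add("O", "LEU", 82L, "O", o82[1], o82[2])
  add("HN", "GLY", 85L, "H", o81[1], o81[2] - t$d_vg[[state]], role = "kinkH")
  add("HN", "THR", 86L, "H", o82[1], o82[2] - t$d_lt[[state]], role = "kinkH")
  add("CG1", "ILE", 84L, "C", NA_real_, NA_real_, role = "i84")
  add("CZ", "PHE", 87L, "C", NA_real_, NA_real_, role = "cz")
  do.call(rbind, rows)
}

# Radial position and z of the Phe87 C-alpha for a state (needed to plant
# the CoF reference per frame).
ca87_position <- function(spec, state, gc) {
  ab <- (gc$alpha_a + spec$templates$angle[[state]]) * pi / 180
  c(r = gc$r_hinge + 4 * gc$rise * sin(ab),
    z = gc$z_hinge - 4 * gc$rise * cos(ab))
}

build_geometry <- function(spec) {
  gc <- geom_const(spec)
  phi <- c(0, 90, 180, 270) * pi / 180
  uvec <- cbind(cos(phi), sin(phi))
  subunits <- c("A", "B", "C", "D")
  tabs <- list()
  for (s in 1:4) {
    tab <- subunit_coords(spec, uvec[s, ], "kinked", gc)
    tab$subunit <- subunits[s]
    tabs[[s]] <- tab
  }
  prot <- do.call(rbind, tabs)
  extra <- function(n, name, resname, element, chain, resid0) {
    if (n == 0L) return(NULL)
    data.frame(atom_name = name, residue_name = resname,
               residue_id = resid0 + seq_len(n) - 1L, element = element,
               x = 0, y = 0, z = 0, role = tolower(resname),
               subunit = chain, stringsAsFactors = FALSE)
  }
  all_tab <- rbind(prot,
                   extra(spec$n_ions, "K", "K", "K", "I", 1L),
                   extra(spec$n_waters, "OW", "SOL", "O", "W", 1L),
                   extra(64L, "P", "LIP", "P", "L", 1L))
  atoms <- data.frame(atom_id = seq_len(nrow(all_tab)) - 1L,
                      atom_name = all_tab$atom_name,
                      residue_name = all_tab$residue_name,
                      residue_id = all_tab$residue_id,
                      subunit = all_tab$subunit,
                      element = all_tab$element,
                      vdw_radius = assign_radii(all_tab$element,
                                                default_radius_table(), 0.17),
                      stringsAsFactors = FALSE)
  list(topology = new_topology(atoms), tab = all_tab, gc = gc, uvec = uvec,
       subunits = subunits)
}

#' Build the synthetic tetramer topology
#'
#' Four-fold pseudo-symmetric channel with outer helix (ending Pro19), pore
#' helix, TVGYG filter (residues 59-63 with backbone O and Thr59 CB/OG1),
#' inner helix (residues 71-98, hinge Gly83, with Val81/Leu82 backbone O,
#' Gly85/Thr86 amide HN, Ile84 and Phe87 side-chain pseudo-atoms), K+ ions,
#' waters, and two lipid phosphate layers. Standard PDB naming, so all
#' descriptor selections resolve. Deterministic: geometry randomness lives
#' in the frames, not the topology.
#'
#' @param spec a [synthetic_spec()]
#' @return a [topology]
#' @export
build_channel_topology <- function(spec) build_geometry(spec)$topology

#' Generate a synthetic trajectory with ground truth
#'
#' Per frame, each subunit's coordinates interpolate to its state template
#' plus isotropic Gaussian noise; the Thr59 O-gamma ring radius follows the
#' planted `og_diag` map of the number of bent subunits; the Phe87
#' side-chain pseudo-atom sits at the planted CoF distance for the
#' subunit's state; the Ile84 pseudo-atom sits at the planted distance from
#' the Thr59 side-chain COM; crossing ions traverse the filter as smooth
#' 2 ns ramps at Poisson times with the configuration-dependent rate; the
#' cavity water count follows the dehydration map; phosphate layers sit at
#' +/- thickness/2. In equilibrium-ion mode (spec$U set) ion z positions
#' are instead Boltzmann-sampled from exp(-U) and no crossings occur.
#'
#' @param spec a [synthetic_spec()]
#' @param states state matrix from [simulate_state_dynamics()] (default:
#'   simulated from the spec seed)
#' @param seed seed for geometry noise, particle placement and event times
#' @return list with `topology`, `frames` (a [frame_series]), and `truth`
#'   (states, per-frame `n_bent`, realized `events`, per-frame crossing
#'   rate `lambda`, cavity water counts, and a parameter echo)
#' @export
generate_trajectory <- function(spec, states = NULL, seed = spec$seed) {
  states <- states %||% simulate_state_dynamics(spec, seed = seed)
  nf <- spec$n_frames
  if (nrow(states) != nf) stop("state matrix length does not match n_frames")
  geo <- build_geometry(spec)
  gc <- geo$gc
  tab <- geo$tab
  na <- nrow(tab)
  n_bent <- as.integer(rowSums(states == "bent"))
  t_ <- spec$templates

  with_seed(seed, {
    # static base: kinked template everywhere, placeholders at 0
    base <- as.matrix(tab[, c("x", "y", "z")])
    base[is.na(base)] <- 0
    arr <- array(base, dim = c(na, 3L, nf))

    # per-subunit dynamic template swap (segment B C-alphas + kink HN)
    for (s in 1:4) {
      sub_rows <- which(tab$subunit == geo$subunits[s])
      dyn_local <- tab$role[sub_rows] %in% c("segB", "kinkH")
      dyn_rows <- sub_rows[dyn_local]
      bent_tab <- subunit_coords(spec, geo$uvec[s, ], "bent", gc)
      bent_xyz <- as.matrix(bent_tab[dyn_local, c("x", "y", "z")])
      bf <- which(states[, s] == "bent")
      if (length(bf))
        arr[dyn_rows, , bf] <- array(bent_xyz, c(length(dyn_rows), 3L, length(bf)))
    }

    # Thr59 O-gamma ring radius from the bent count
    r_og <- t_$og_diag[n_bent + 1L] / 2
    og_rows <- which(tab$role == "og1")
    for (s in 1:4) {
      arr[og_rows[s], 1L, ] <- gc$x0 + r_og * geo$uvec[s, 1]
      arr[og_rows[s], 2L, ] <- gc$y0 + r_og * geo$uvec[s, 2]
      arr[og_rows[s], 3L, ] <- gc$z_og
    }

    # Ile84 side-chain pseudo-atom at the planted distance from the Thr59
    # side-chain COM (CB static + OG1 moving with the ring)
    mC <- element_mass("C"); mO <- element_mass("O")
    i84_rows <- which(tab$role == "i84")
    for (s in 1:4) {
      r_com <- (mC * gc$r_cb59 + mO * r_og) / (mC + mO)
      z_com <- (mC * gc$z_cb59 + mO * gc$z_og) / (mC + mO)
      d <- ifelse(states[, s] == "bent", t_$d_i84t59[["bent"]],
                  t_$d_i84t59[["kinked"]])
      arr[i84_rows[s], 1L, ] <- gc$x0 + r_com * geo$uvec[s, 1]
      arr[i84_rows[s], 2L, ] <- gc$y0 + r_com * geo$uvec[s, 2]
      arr[i84_rows[s], 3L, ] <- z_com - d
    }

    # Phe87 side chain at the planted CoF distance from the C-alpha CoF
    ca87 <- sapply(c("kinked", "bent"), function(st) ca87_position(spec, st, gc))
    cz_rows <- which(tab$role == "cz")
    bentm <- states == "bent"
    r87 <- matrix(ca87["r", (bentm) + 1L], nf, 4L)
    z87 <- matrix(ca87["z", (bentm) + 1L], nf, 4L)
    cof_x <- gc$x0 + (r87 %*% geo$uvec[, 1]) / 4
    cof_y <- gc$y0 + (r87 %*% geo$uvec[, 2]) / 4
    cof_z <- rowMeans(z87)
    for (s in 1:4) {
      d <- ifelse(bentm[, s], t_$d_cof[["bent"]], t_$d_cof[["kinked"]])
      arr[cz_rows[s], 1L, ] <- cof_x + d * geo$uvec[s, 1]
      arr[cz_rows[s], 2L, ] <- cof_y + d * geo$uvec[s, 2]
      arr[cz_rows[s], 3L, ] <- cof_z
    }

    # lipid phosphate layers
    lip_rows <- which(tab$role == "lip")
    grid <- as.matrix(expand.grid(x = seq(0.4, spec$box[1] - 0.4, length.out = 8),
                                  y = seq(0.4, spec$box[2] - 0.4, length.out = 8)))
    rad <- sqrt((grid[, 1] - gc$x0)^2 + (grid[, 2] - gc$y0)^2)
    grid <- grid[order(-rad), ][seq_len(32L), ]
    for (leaf in 0:1) {
      rows <- lip_rows[leaf * 32L + seq_len(32L)]
      arr[rows, 1L, ] <- grid[, 1]
      arr[rows, 2L, ] <- grid[, 2]
      arr[rows, 3L, ] <- gc$zc + (if (leaf == 0) -1 else 1) * spec$thickness / 2
    }

    # waters: cavity pool with dehydration, rest in the bulk
    wat_rows <- which(tab$role == "sol")
    n_cav_pool <- max(spec$cavity_water_map)
    cav_r <- sqrt(runif(n_cav_pool)) * 0.45
    cav_phi <- runif(n_cav_pool, 0, 2 * pi)
    cav_pos <- cbind(gc$x0 + cav_r * cos(cav_phi), gc$y0 + cav_r * sin(cav_phi),
                     runif(n_cav_pool, 4.2, 5.4))
    bulk_pos <- function(n) {
      phi <- runif(n, 0, 2 * pi)
      r <- runif(n, 2.0, 3.0)
      cbind(gc$x0 + r * cos(phi), gc$y0 + r * sin(phi),
            runif(n, 0.5, spec$box[3] - 0.5))
    }
    cav_alt <- bulk_pos(n_cav_pool)
    n_cav_t <- spec$cavity_water_map[n_bent + 1L]
    for (i in seq_len(n_cav_pool)) {
      active <- n_cav_t >= i
      arr[wat_rows[i], 1L, ] <- ifelse(active, cav_pos[i, 1], cav_alt[i, 1])
      arr[wat_rows[i], 2L, ] <- ifelse(active, cav_pos[i, 2], cav_alt[i, 2])
      arr[wat_rows[i], 3L, ] <- ifelse(active, cav_pos[i, 3], cav_alt[i, 3])
    }
    if (spec$n_waters > n_cav_pool) {
      bp <- bulk_pos(spec$n_waters - n_cav_pool)
      rows <- wat_rows[(n_cav_pool + 1L):spec$n_waters]
      arr[rows, 1L, ] <- bp[, 1]; arr[rows, 2L, ] <- bp[, 2]
      arr[rows, 3L, ] <- bp[, 3]
    }

    # ions
    ion_rows <- which(tab$role == "k")
    lambda <- spec$lambda_by_config[n_bent + 1L]
    events <- data.frame(ion_id = integer(), entry_frame = integer(),
                         exit_frame = integer(), direction = integer())
    if (!is.null(spec$U)) {
      # equilibrium-ion mode: Boltzmann-sample z from exp(-U)
      zg <- seq(spec$u_z_range[1], spec$u_z_range[2], by = 0.002)
      w <- exp(-spec$U(zg))
      for (i in seq_along(ion_rows)) {
        zrel <- sample(zg, nf, replace = TRUE, prob = w) +
          runif(nf, -0.001, 0.001)
        phi <- runif(nf, 0, 2 * pi)
        r <- sqrt(runif(nf)) * 0.4
        arr[ion_rows[i], 1L, ] <- gc$x0 + r * cos(phi)
        arr[ion_rows[i], 2L, ] <- gc$y0 + r * sin(phi)
        arr[ion_rows[i], 3L, ] <- gc$z_og + zrel
      }
      lambda <- rep(0, nf)
    } else {
      nc <- max(2L, round(spec$crossing_time_ns / spec$dt))
      pool <- seq_len(spec$n_crossing)
      park_phi <- runif(spec$n_ions, 0, 2 * pi)
      # crossing pool parks near the axis below the filter
      for (i in pool) {
        arr[ion_rows[i], 1L, ] <- gc$x0 + 0.12 * cos(park_phi[i])
        arr[ion_rows[i], 2L, ] <- gc$y0 + 0.12 * sin(park_phi[i])
        arr[ion_rows[i], 3L, ] <- gc$park_below
      }
      if (spec$n_ions > spec$n_crossing) {
        bulk <- (spec$n_crossing + 1L):spec$n_ions
        bp <- bulk_pos(length(bulk))
        arr[ion_rows[bulk], 1L, ] <- bp[, 1]
        arr[ion_rows[bulk], 2L, ] <- bp[, 2]
        arr[ion_rows[bulk], 3L, ] <- bp[, 3]
      }
      p <- lambda * spec$dt * 1e-3  # events per frame
      want <- runif(nf) < p
      busy_until <- rep(0L, spec$n_crossing)
      ramp <- seq(gc$park_below, gc$park_above, length.out = nc)
      ev <- list()
      for (f in which(want)) {
        if (f + nc - 1L > nf) next
        free <- which(busy_until < f)
        if (length(free) == 0L) next
        i <- free[1L]
        arr[ion_rows[i], 3L, f:(f + nc - 1L)] <- ramp
        if (f + nc <= nf)  # stay above until (possibly) reused
          arr[ion_rows[i], 3L, (f + nc):nf] <- gc$park_above
        busy_until[i] <- f + nc
        ev[[length(ev) + 1L]] <- data.frame(ion_id = i, entry_frame = f,
                                            exit_frame = f + nc - 1L,
                                            direction = 1L)
      }
      if (length(ev)) events <- do.call(rbind, ev)
    }

    # noise: protein sigma from the spec; solvent jitter is fixed
    sig <- rep(spec$noise_sigma, na)
    sig[tab$role == "k"] <- 0.02
    sig[tab$role == "sol"] <- 0.03
    sig[tab$role == "lip"] <- 0.02
    arr <- arr + array(rnorm(na * 3L * nf), c(na, 3L, nf)) * sig

    frames <- frame_series(arr, spec$box, times = (seq_len(nf) - 1L) * spec$dt)
    truth <- list(states = states, n_bent = n_bent,
                  f_bent = mean(states == "bent"), events = events,
                  lambda = lambda, cavity_waters = if (is.null(spec$U))
                    spec$cavity_water_map[n_bent + 1L] else NULL,
                  voltage_mV = voltage_from_field(spec$E_field, spec$box[3]),
                  spec = spec)
    list(topology = geo$topology, frames = frames, truth = truth)
  })
}

#' Write a generated trajectory plus its ground truth to disk
#'
#' Emits topology (PDB), trajectory (DCD or multi-model PDB), ground truth
#' (JSON) and the generating spec (YAML) under a common prefix.
#'
#' @param gen result of [generate_trajectory()]
#' @param prefix output path prefix
#' @param format trajectory format, "dcd" or "pdb"
#' @return named vector of the files written, invisibly
#' @export
write_synthetic <- function(gen, prefix, format = c("dcd", "pdb")) {
  format <- match.arg(format)
  files <- c(topology = paste0(prefix, "_top.pdb"),
             trajectory = paste0(prefix, "_traj.", format),
             truth = paste0(prefix, "_truth.json"),
             spec = paste0(prefix, "_spec.yaml"))
  top_frame <- frame_series(gen$frames$coords[, , 1, drop = FALSE],
                            gen$frames$box[1, ])
  write_frames(top_frame, gen$topology, files[["topology"]], format = "pdb")
  write_frames(gen$frames, gen$topology, files[["trajectory"]], format = format)
  truth <- gen$truth
  truth$spec <- NULL
  truth$states <- apply(gen$truth$states, 2L, paste, collapse = "")
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, digits = NA)
  sp <- gen$truth$spec
  sp$U <- NULL
  yaml::write_yaml(unclass(sp), files[["spec"]])
  invisible(files)
}

#' Conduction-group generator presets
#'
#' Named parameter sets planting the three current/bent-fraction groups and
#' the all-bent dewetted channel. All share one crosstalk map (crossing
#' rate vs number of bent subunits, suppressed at both symmetric extremes)
#' and differ in the gating rates (hence the stationary bent fraction) and
#' membrane thickness: high_current (bent fraction 0.30, thin-optimal
#' membrane, ~6 pA scale), mid_current (0.125, ~4 pA), low_current (0.03,
#' thick membrane, ~1 pA), and all_bent_dewetted (bent fraction 1: wide
#' open filter but a dehydrated cavity, with currents well below the
#' asymmetric optimum).
#'
#' @param name preset name
#' @param n_frames,dt,seed overrides passed to [synthetic_spec()]
#' @return a `synthetic_spec`
#' @export
preset_conduction_group <- function(name = c("high_current", "mid_current",
                                       "low_current", "all_bent_dewetted"),
                              n_frames = 4000L, dt = 0.1, seed = 1L) {
  name <- match.arg(name)
  pars <- switch(name,
    high_current = list(k_kb = 0.015, k_bk = 0.035, thickness = 3.6),
    mid_current = list(k_kb = 0.010, k_bk = 0.070, thickness = 3.5),
    low_current = list(k_kb = 0.004, k_bk = 0.1293, thickness = 4.6),
    all_bent_dewetted = list(k_kb = 0.5, k_bk = 0, thickness = 3.9))
  synthetic_spec(n_frames = n_frames, dt = dt, seed = seed,
                 k_kb = pars$k_kb, k_bk = pars$k_bk,
                 thickness = pars$thickness)
}
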