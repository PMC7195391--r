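# Axial density / "free energy" profiles, pore radius, membrane thickness.

test_that("axial density localizes a fixed ion and flags empty input", {
  gen <- generate_trajectory(quick_spec(n_frames = 5L, noise_sigma = 0))
  fr <- gen$frames
  ions <- select(gen$topology, "resname K")$indices
  fr$coords[ions + 1L, , ] <- 0.3          # out of the cylinder
  fr$coords[ions[1] + 1L, 1L, ] <- 3.25
  fr$coords[ions[1] + 1L, 2L, ] <- 3.25
  fr$coords[ions[1] + 1L, 3L, ] <- 5.6 + 0.5  # z = +0.5 relative to O-gamma
  prof <- axial_density(fr, gen$topology, "resname K")
  expect_equal(sum(prof$density > 0), 1L)
  expect_equal(prof$z_centers[which(prof$density > 0)], 0.5, tolerance = 0.051)
  expect_equal(sum(prof$counts), 5)
  expect_error(suppressWarnings(axial_density(fr, gen$topology, "resname NOPE")),
               "empty selection")
})

test_that("free energy inversion is flat for uniform density and masks zeros", {
  prof <- structure(list(z_centers = 1:5 / 10, counts = rep(40, 5),
                         density = rep(4, 5), n_frames = 10, F = NULL),
                    class = "axial_profile")
  out <- free_energy_profile(prof)
  expect_equal(out$F, rep(0, 5))
  prof$density[3] <- 0
  out2 <- free_energy_profile(prof)
  expect_true(is.na(out2$F[3]))
  expect_false(any(is.infinite(out2$F), na.rm = TRUE))
  prof$density[] <- 0
  expect_error(free_energy_profile(prof), "all-zero")
})

test_that("Boltzmann-sampled ions recover a planted harmonic potential", {
  U <- function(z) 2 * (z - 0.3)^2
  spec <- synthetic_spec(n_frames = 1500L, n_ions = 40L, seed = 31L, U = U)
  gen <- generate_trajectory(spec)
  prof <- free_energy_profile(
    axial_density(gen$frames, gen$topology, "resname K",
                  z_range = c(-1.6, 1.6)))
  ok <- prof$counts >= 100
  expect_gt(sum(ok), 20L)
  resid <- prof$F[ok] - U(prof$z_centers[ok])
  expect_lt(sqrt(mean((resid - mean(resid))^2)), 0.15)
})

test_that("barrier heights read off the profile with and without reference", {
  prof <- structure(list(z_centers = c(0.1, 0.2, 0.3, 0.4),
                         counts = c(400, 120, 2, 296),
                         density = c(4, 1.2, 0.02, 2.96), n_frames = 100,
                         F = c(0, 1.2, 5.1, 0.3)),
                    class = "axial_profile")
  expect_equal(barrier_height(prof, c(0.25, 0.35)), 5.1)
  expect_equal(barrier_height(prof, c(0.25, 0.45), reference = c(0.05, 0.15)),
               5.1 - 0)
  flat <- structure(list(z_centers = 1:4 / 10, counts = rep(10, 4),
                         density = rep(1, 4), n_frames = 10,
                         F = rep(0, 4)), class = "axial_profile")
  expect_equal(barrier_height(flat, c(0.1, 0.4)), 0)
  prof$F[2:3] <- NA
  expect_error(barrier_height(prof, c(0.15, 0.35)), "masked")
})

test_that("a planted Gaussian barrier is recovered at its height", {
  h <- 5.1
  U <- function(z) h * exp(-(z / 0.25)^2)
  spec <- synthetic_spec(n_frames = 2500L, n_ions = 40L, seed = 33L, U = U)
  gen <- generate_trajectory(spec)
  prof <- free_energy_profile(
    axial_density(gen$frames, gen$topology, "resname K",
                  z_range = c(-1.6, 1.6)))
  expect_equal(barrier_height(prof, c(-0.3, 0.3)), h, tolerance = 0.2 / h)
})

test_that("pore radius matches analytic rings, cones and empty slices", {
  # ring of carbons (vdw 0.17) at xy-radius 1.0
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  mk_ring <- function(r, z) cbind(5 + r * cos(ang), 5 + r * sin(ang), z)
  ring_top <- function(n) {
    # filter CA atoms define the axis; add them far above the probed range
    fil <- mini_topology(rep("CA", 4L), rep("GLY", 4L), rep(61L, 4L),
                         c("A", "B", "C", "D"))
    og <- mini_topology("OG1", "THR", 59L, "A")
    atoms <- rbind(fil$atoms,
                   transform(og$atoms, atom_id = 4L),
                   data.frame(atom_id = 4L + seq_len(n),
                              atom_name = "C1", residue_name = "RNG",
                              residue_id = 100L + seq_len(n), subunit = "A",
                              element = "C", vdw_radius = 0.17))
    atoms$atom_id <- seq_len(nrow(atoms)) - 1L
    kinkgate:::new_topology(atoms)
  }
  n <- 3L * length(ang)
  top <- ring_top(n)
  xyz <- matrix(0, top$n_atoms, 3L)
  xyz[1:4, ] <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6), 8)   # axis at (5,5)
  xyz[5L, ] <- c(5, 5, 8)                                 # O-gamma plane z=8
  xyz[5L + seq_len(length(ang)), ] <- mk_ring(1.0, 7.0)   # z_rel = -1
  xyz[5L + length(ang) + seq_len(length(ang)), ] <- mk_ring(1.2, 6.5)
  xyz[5L + 2L * length(ang) + seq_len(length(ang)), ] <- mk_ring(1.4, 6.0)
  fr <- frame_series(array(xyz, c(top$n_atoms, 3L, 1L)), c(10, 10, 10))
  prof <- pore_radius_profile(fr, top, expression = "resname RNG",
                              bin_width = 0.5, slab_half_width = 0.1,
                              z_range = c(-2, -1), r_max = 2)
  expect_equal(prof$radius[prof$z_centers == -1], 1.0 - 0.17,
               tolerance = 1e-6)
  expect_equal(prof$radius[prof$z_centers == -1.5], 1.2 - 0.17,
               tolerance = 1e-6)
  expect_equal(prof$radius[prof$z_centers == -2], 1.4 - 0.17,
               tolerance = 1e-6)
  # empty slice -> r_max, flagged
  prof2 <- pore_radius_profile(fr, top, expression = "resname RNG",
                               bin_width = 0.5, slab_half_width = 0.1,
                               z_range = c(0.5, 1), r_max = 2)
  expect_equal(unique(prof2$radius), 2)
  expect_equal(unique(prof2$empty_fraction), 1)
})

test_that("the bent state constricts the cavity by the planted amount", {
  mk <- function(kk, kb) {
    spec <- quick_spec(n_frames = 150L, k_kb = kk, k_bk = kb,
                       noise_sigma = 0.005)
    gen <- generate_trajectory(spec)
    prof <- pore_radius_profile(gen$frames, gen$topology, stride = 5L,
                                z_range = c(-2, -1.5))
    min(prof$radius)
  }
  r_kinked <- mk(0, 1)    # all kinked
  r_bent <- mk(1, 0)      # all bent
  planted <- 0.836 - 0.666
  expect_equal(r_kinked - r_bent, planted, tolerance = 0.03 / planted)
})

test_that("profiles are invariant under rigid z-translation", {
  gen <- generate_trajectory(quick_spec(n_frames = 30L))
  prof <- axial_density(gen$frames, gen$topology, "resname K")
  moved <- transform_frames(gen$frames, diag(3), c(0, 0, 1.3))
  moved$box <- gen$frames$box + 5  # box change must not matter either
  prof2 <- axial_density(moved, gen$topology, "resname K")
  expect_equal(prof2$density, prof$density)
  pr <- pore_radius_profile(gen$frames, gen$topology, stride = 10L)
  pr2 <- pore_radius_profile(moved, gen$topology, stride = 10L)
  expect_equal(pr2$radius, pr$radius, tolerance = 1e-10)
})

test_that("membrane thickness splits leaflets and flags monolayers", {
  n <- 16L
  top <- mini_topology(rep("P", 2L * n), rep("LIP", 2L * n),
                       seq_len(2L * n), rep("L", 2L * n), element = rep("P", 2L * n))
  xyz <- cbind(runif(2 * n, 0, 6), runif(2 * n, 0, 6),
               rep(c(4.6 - 1.8, 4.6 + 1.8), each = n))
  fr <- frame_series(array(xyz, c(2L * n, 3L, 1L)), c(6.5, 6.5, 9.2))
  th <- membrane_thickness(fr, top)
  expect_equal(th$thickness, 3.6, tolerance = 1e-12)
  # noisy leaflets: mean within 3 sem of the planted value
  set.seed(8)
  nf <- 50L
  coords <- array(NA_real_, c(2L * n, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- xyz + cbind(0, 0, rnorm(2 * n, 0, 0.1))
  frn <- frame_series(coords, c(6.5, 6.5, 9.2))
  thn <- membrane_thickness(frn, top)
  expect_lt(abs(thn$thickness - 3.6), 3 * thn$sem + 0.02)
  # monolayer
  xyz1 <- xyz; xyz1[, 3] <- 2.8
  fr1 <- frame_series(array(xyz1, c(2L * n, 3L, 1L)), c(6.5, 6.5, 9.2))
  expect_error(membrane_thickness(fr1, top), "bilayer")
})

test_that("the generator plants the configured membrane thickness", {
  gen <- generate_trajectory(quick_spec(n_frames = 50L, thickness = 3.9))
  th <- membrane_thickness(gen$frames, gen$topology)
  expect_equal(th$thickness, 3.9, tolerance = 0.01)
})
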