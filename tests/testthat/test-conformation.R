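# Gating descriptors and the kinked/bent state classifier.

# topology with Val81 O and Gly85 HN per subunit at given coordinates
kink_pair_fixture <- function(o_xyz, h_xyz, box = c(10, 10, 9.2)) {
  top <- mini_topology(rep(c("O", "HN"), 4L),
                       rep(c("VAL", "GLY"), 4L),
                       rep(c(81L, 85L), 4L),
                       rep(c("A", "B", "C", "D"), each = 2L))
  coords <- array(NA_real_, c(8L, 3L, 1L))
  for (s in 0:3) {
    coords[2 * s + 1L, , 1L] <- o_xyz
    coords[2 * s + 2L, , 1L] <- h_xyz
  }
  list(topology = top, frames = frame_series(coords, box))
}

test_that("hbond_distance measures the O..HN distance with minimum image", {
  fx <- kink_pair_fixture(c(0, 0, 0), c(0, 0, 0.2))
  expect_equal(unname(hbond_distance(fx$frames, fx$topology)[1, ]),
               rep(0.2, 4L))
  # split across the periodic boundary: O at z=0.1, H at z=Lz-0.05
  fx2 <- kink_pair_fixture(c(1, 1, 0.1), c(1, 1, 9.2 - 0.05))
  expect_equal(unname(hbond_distance(fx2$frames, fx2$topology)[1, ]),
               rep(0.15, 4L), tolerance = 1e-12)
})

test_that("heavy-atom topologies get a clear error and an O-N fallback", {
  top <- mini_topology(rep(c("O", "N"), 4L), rep(c("VAL", "GLY"), 4L),
                       rep(c(81L, 85L), 4L), rep(c("A", "B", "C", "D"), each = 2L))
  # interleaved O/N atoms 0.35 nm apart
  xyz <- matrix(0, 8, 3)
  xyz[seq(2, 8, 2), 3] <- 0.35
  fr <- frame_series(array(xyz, c(8, 3, 1)), c(10, 10, 10))
  expect_error(hbond_distance(fr, top), "use_heavy")
  d <- hbond_distance(fr, top, use_heavy = TRUE)
  expect_equal(unname(d[1, ]), rep(0.35, 4L))
})

test_that("distance descriptors recover generator ground truth per state", {
  spec <- quick_spec(noise_sigma = 0.005, k_kb = 0.3, k_bk = 0.3)
  gen <- generate_trajectory(spec)
  st <- gen$truth$states
  d_vg <- hbond_distance(gen$frames, gen$topology)
  expect_equal(mean(d_vg[st == "kinked"]), 0.55, tolerance = 0.02)
  expect_equal(mean(d_vg[st == "bent"]), 0.25, tolerance = 0.02)
  d_i84 <- sidechain_com_distance(gen$frames, gen$topology)
  expect_equal(mean(d_i84[st == "kinked"]), 0.54, tolerance = 0.01)
  expect_equal(mean(d_i84[st == "bent"]), 0.59, tolerance = 0.01)
  d_cof <- phe87_cof_distance(gen$frames, gen$topology)
  expect_equal(mean(d_cof[st == "kinked"]), 0.836, tolerance = 0.01)
  expect_equal(mean(d_cof[st == "bent"]), 0.666, tolerance = 0.01)
})

test_that("bending angle is exact for collinear and constructed geometries", {
  # straight helix: both segments on one line -> 0 degrees
  n <- 30L
  top <- mini_topology(rep("CA", n), rep("ALA", n), 71:100,
                       rep("A", n))
  # need 4 subunits for the descriptor surface: build via generator instead
  spec <- quick_spec(n_frames = 2L, noise_sigma = 0,
                     templates = list(angle = c(kinked = 0, bent = 0)))
  gen <- generate_trajectory(spec)
  ang0 <- bending_angle(gen$frames, gen$topology)
  expect_lt(max(ang0), 1e-6)
  # planted 43/30 degree templates are recovered
  spec2 <- quick_spec(noise_sigma = 0.004, k_kb = 0.3, k_bk = 0.3)
  gen2 <- generate_trajectory(spec2)
  st <- gen2$truth$states
  ang <- bending_angle(gen2$frames, gen2$topology)
  expect_equal(mean(ang[st == "kinked"]), 43, tolerance = 1)
  expect_equal(mean(ang[st == "bent"]), 30, tolerance = 1)
})

test_that("bending angle survives ideal-helix geometry at 43 degrees", {
  # two ideal helical segments whose axes subtend 43 degrees
  helix <- function(n, axis_origin, R, phase = 0) {
    t(vapply(seq_len(n), function(i) {
      local_p <- c(0.23 * cos(phase + i * 100 * pi / 180),
                   0.23 * sin(phase + i * 100 * pi / 180), 0.15 * i)
      axis_origin + R %*% local_p
    }, numeric(3)))
  }
  th <- 43 * pi / 180
  Rz <- diag(3)
  Rrot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  seg_a <- helix(12L, c(0, 0, 0), Rz)
  seg_b <- helix(14L, seg_a[12L, ], Rrot)
  pts <- rbind(seg_a, matrix(seg_a[12L, ], 1L), seg_b)  # hinge CA between
  n <- nrow(pts)
  top <- mini_topology(rep("CA", 4L * n), rep("ALA", 4L * n),
                       rep(71:(70L + n), 4L),
                       rep(c("A", "B", "C", "D"), each = n))
  coords <- array(NA_real_, c(4L * n, 3L, 1L))
  for (s in 0:3) coords[s * n + seq_len(n), , 1L] <- pts + 5
  fr <- frame_series(coords, c(50, 50, 50))
  ang <- bending_angle(fr, top, helix_range = c(71L, 70L + n),
                       hinge = 83L)
  expect_equal(unname(ang[1L, ]), rep(43, 4L), tolerance = 1)
})

test_that("bending angle is invariant under rigid motions", {
  gen <- generate_trajectory(quick_spec(n_frames = 5L))
  ang <- bending_angle(gen$frames, gen$topology)
  set.seed(3)
  for (i in 1:3) {
    moved <- transform_frames(gen$frames, random_rotation(), rnorm(3))
    expect_equal(bending_angle(moved, gen$topology), ang, tolerance = 1e-8)
  }
})

test_that("distance descriptors are minimum-image correct", {
  gen <- generate_trajectory(quick_spec(n_frames = 3L))
  d0 <- hbond_distance(gen$frames, gen$topology)
  shifted <- gen$frames
  # translate one atom (a Gly85 HN) by integer box vectors
  sel <- select(gen$topology, "subunit B and resid 85 and name HN")
  shifted$coords[sel$indices + 1L, 3L, ] <-
    shifted$coords[sel$indices + 1L, 3L, ] + 2 * gen$frames$box[1, 3]
  shifted$coords[sel$indices + 1L, 1L, ] <-
    shifted$coords[sel$indices + 1L, 1L, ] - gen$frames$box[1, 1]
  expect_equal(hbond_distance(shifted, gen$topology), d0, tolerance = 1e-12)
})

test_that("classify_state applies thresholds, hysteresis and f_bent", {
  const <- function(v) matrix(v, 10L, 4L,
                              dimnames = list(NULL, c("A", "B", "C", "D")))
  expect_equal(classify_state(const(0.20))$f_bent, 1)
  expect_equal(classify_state(const(0.55))$f_bent, 0)
  # one permanently bent subunit -> tetramer f_bent 25%
  d <- const(0.55); d[, "A"] <- 0.20
  tr <- classify_state(d)
  expect_equal(tr$f_bent, 0.25)
  expect_equal(unname(tr$f_bent_by_subunit), c(1, 0, 0, 0))
  expect_equal(unique(tr$n_bent), 1L)
  # hysteresis trace: 0.20 -> 0.35 -> 0.55 -> 0.35
  tr2 <- classify_state(matrix(c(0.20, 0.35, 0.55, 0.35), 4L, 1L))
  expect_equal(unname(tr2$labels[, 1]), c("bent", "bent", "kinked", "kinked"))
  # single-cutoff mode relabels the return into the band
  tr3 <- classify_state(matrix(c(0.20, 0.35, 0.55, 0.35), 4L, 1L),
                        hysteresis = FALSE)
  expect_equal(unname(tr3$labels[, 1]), c("bent", "bent", "kinked", "bent"))
  expect_error(classify_state(const(NaN)), "non-finite")
})

test_that("classifier recovers planted states at wide template separation", {
  # noise sigma 0.04 -> d_VG sd ~0.057 nm; templates 0.30 nm apart (>5 sigma)
  spec <- quick_spec(n_frames = 1000L, noise_sigma = 0.04,
                     k_kb = 0.2, k_bk = 0.2)
  gen <- generate_trajectory(spec)
  tr <- classify_state(hbond_distance(gen$frames, gen$topology))
  expect_gte(mean(tr$labels == gen$truth$states), 0.99)
})

test_that("f_bent of stationary chains converges to k_kb/(k_kb+k_bk)", {
  for (rates in list(c(0.2, 0.2), c(0.12, 0.28), c(0.012, 0.388))) {
    a <- rates[1]; b <- rates[2]
    f <- a / (a + b)
    spec <- synthetic_spec(n_frames = 20000L, dt = 0.1, seed = 101L,
                           k_kb = a, k_bk = b)
    st <- simulate_state_dynamics(spec)
    got <- mean(st == "bent")
    # 3 sigma for the time average of 4 chains with correlation time
    # 1/(a+b): var = f(1-f) * 2*tau / T / 4
    tol <- 3 * sqrt(f * (1 - f) * 2 * (1 / (a + b)) / (20000 * 0.1) / 4)
    expect_lt(abs(got - f), tol)
  }
})

test_that("cross-subunit ring distances match square geometry", {
  fx <- ring_fixture(square_points(0.36))
  expect_equal(cross_subunit_distance(fx$frames, fx$topology,
                                      "resid 19 and name CA"),
               0.36 * sqrt(2), tolerance = 1e-12)
  expect_equal(cross_subunit_distance(fx$frames, fx$topology,
                                      "resid 19 and name CA", pairing = "all"),
               (4 * 0.36 + 2 * 0.36 * sqrt(2)) / 6, tolerance = 1e-12)
})

test_that("planted Thr59 ring opening is recovered per configuration", {
  spec <- quick_spec(n_frames = 600L, noise_sigma = 0.005, k_kb = 0.3,
                     k_bk = 0.3)
  gen <- generate_trajectory(spec)
  og <- cross_subunit_distance(gen$frames, gen$topology,
                               "resid 59 and name OG1")
  nb <- gen$truth$n_bent
  planted <- gen$truth$spec$templates$og_diag
  for (k in 0:4) {
    if (sum(nb == k) < 20L) next
    expect_equal(mean(og[nb == k]), planted[k + 1L], tolerance = 0.005)
  }
})

test_that("side-chain COM distances handle point side chains and glycine", {
  # two single-atom side chains 0.54 nm apart in each subunit
  top <- mini_topology(rep(c("CG1", "OG1"), 4L), rep(c("ILE", "THR"), 4L),
                       rep(c(84L, 59L), 4L), rep(c("A", "B", "C", "D"), each = 2L))
  xyz <- matrix(0, 8L, 3L)
  xyz[, 1] <- rep(c(1, 1), 4L) + 0.3 * rep(0:3, each = 2L)
  xyz[seq(2L, 8L, 2L), 3L] <- 0.54
  fr <- frame_series(array(xyz, c(8L, 3L, 1L)), c(10, 10, 10))
  d <- sidechain_com_distance(fr, top)
  expect_equal(unname(d[1L, ]), rep(0.54, 4L))
  # identical COMs -> 0
  xyz[seq(2L, 8L, 2L), 3L] <- 0
  fr0 <- frame_series(array(xyz, c(8L, 3L, 1L)), c(10, 10, 10))
  expect_equal(unname(sidechain_com_distance(fr0, top)[1L, ]), rep(0, 4L))
  # glycine has no side chain
  topg <- mini_topology(rep(c("CG1", "CA"), 4L), rep(c("ILE", "GLY"), 4L),
                        rep(c(84L, 59L), 4L), rep(c("A", "B", "C", "D"), each = 2L))
  expect_error(sidechain_com_distance(fr, topg), "side-chain")
})

test_that("com_ring_distance gives the diameter for COMs on a circle", {
  r <- 0.825
  ang <- c(0, 90, 180, 270) * pi / 180
  pts <- cbind(5 + r * cos(ang), 5 + r * sin(ang), 2)
  fx <- ring_fixture(pts, resid = 84L, name = "CG1", resname = "ILE")
  expect_equal(com_ring_distance(fx$frames, fx$topology), 2 * r,
               tolerance = 1e-12)
  # degenerate: all COMs coincident
  fx0 <- ring_fixture(matrix(rep(c(5, 5, 2), 4L), 4L, byrow = TRUE),
                      resid = 84L, name = "CG1", resname = "ILE")
  expect_equal(com_ring_distance(fx0$frames, fx0$topology), 0)
})

test_that("phe87_cof_distance measures side chain vs C-alpha-ring COM", {
  nm <- rep(c("CA", "CZ"), 4L)
  top <- mini_topology(nm, rep("PHE", 8L), rep(87L, 8L),
                       rep(c("A", "B", "C", "D"), each = 2L))
  ang <- c(0, 90, 180, 270) * pi / 180
  xyz <- matrix(0, 8L, 3L)
  xyz[seq(1L, 8L, 2L), 1:2] <- cbind(5 + cos(ang), 5 + sin(ang))  # CA ring
  xyz[seq(2L, 8L, 2L), 1:2] <- cbind(5 + 0.8 * cos(ang), 5 + 0.8 * sin(ang))
  fr <- frame_series(array(xyz, c(8L, 3L, 1L)), c(10, 10, 10))
  d <- phe87_cof_distance(fr, top)
  expect_equal(unname(d[1L, ]), rep(0.8, 4L), tolerance = 1e-12)
  # side chain at the ring centre -> 0 (fully in the cavity)
  xyz[seq(2L, 8L, 2L), 1:2] <- 5
  fr0 <- frame_series(array(xyz, c(8L, 3L, 1L)), c(10, 10, 10))
  expect_equal(max(phe87_cof_distance(fr0, top)), 0)
})

test_that("histogram2d counts, normalizes and separates planted modes", {
  h <- histogram2d(rep(0.5, 10), rep(1.5, 10), 0:2, 0:2)
  expect_equal(sum(h$z), 10)
  expect_equal(h$z[1, 2], 10)
  hn <- histogram2d(runif(100), runif(100), seq(0, 1, 0.25),
                    seq(0, 1, 0.25), normalize = TRUE)
  expect_equal(sum(hn$z), 1)
  expect_error(histogram2d(1:3, 1:4, 0:2, 0:2), "same length")
  # two-state mixture shows two modes at the planted (theta, d_VG) centres
  gen <- generate_trajectory(quick_spec(n_frames = 400L, k_kb = 0.3,
                                        k_bk = 0.3, noise_sigma = 0.005))
  ang <- bending_angle(gen$frames, gen$topology)
  dvg <- hbond_distance(gen$frames, gen$topology)
  h2 <- histogram2d(as.vector(ang), as.vector(dvg), seq(20.5, 50.5, 3),
                    seq(0.125, 0.725, 0.05))
  peaks <- which(h2$z >= 0.5 * max(h2$z), arr.ind = TRUE)
  cents <- cbind(h2$x_mid[peaks[, 1]], h2$y_mid[peaks[, 2]])
  expect_true(any(abs(cents[, 1] - 43) < 3 & abs(cents[, 2] - 0.55) < 0.05))
  expect_true(any(abs(cents[, 1] - 30) < 3 & abs(cents[, 2] - 0.25) < 0.05))
})
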