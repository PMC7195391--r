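# Superposition and PLS functional mode analysis.

test_that("superpose removes rigid motions down to numerical noise", {
  gen <- generate_trajectory(quick_spec(n_frames = 6L))
  fr <- gen$frames
  set.seed(4)
  R <- random_rotation(); shift <- rnorm(3)
  moved <- transform_frames(fr, R, shift)
  # aligning the moved series equals aligning the original and then
  # applying the same rigid motion (the reference frame moved too)
  al <- superpose(moved, gen$topology, "name CA")
  ref_al <- transform_frames(superpose(fr, gen$topology, "name CA"), R, shift)
  expect_equal(al$coords, ref_al$coords, tolerance = 1e-8)
  # identity input is unchanged on the fit selection
  ca <- select(gen$topology, "name CA")$indices + 1L
  same <- superpose(fr, gen$topology, "name CA", reference_frame = 1L)
  rmsd1 <- sqrt(mean((same$coords[ca, , 1] - fr$coords[ca, , 1])^2))
  expect_lt(rmsd1, 1e-10)
  # collinear fit selections are rejected
  line_fx <- ring_fixture(cbind(1:4, 1:4, 1:4))
  expect_error(superpose(line_fx$frames, line_fx$topology, "name CA"),
               "collinear")
})

test_that("superpose agrees with the bio3d fitting oracle", {
  gen <- generate_trajectory(quick_spec(n_frames = 8L))
  top <- gen$topology
  ca <- select(top, "name CA")$indices + 1L
  al <- superpose(gen$frames, top, "name CA")
  xyz <- t(matrix(aperm(gen$frames$coords[ca, , , drop = FALSE] * 10,
                        c(2, 1, 3)), ncol = 8L))
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz[1, ], xyz))
  ours <- t(matrix(aperm(al$coords[ca, , , drop = FALSE] * 10,
                         c(2, 1, 3)), ncol = 8L))
  # same post-fit RMSD per frame (alignment target differs by a constant)
  rms_b <- sqrt(rowMeans((fitted - rep(fitted[1, ], each = 8L))^2))
  rms_o <- sqrt(rowMeans((ours - rep(ours[1, ], each = 8L))^2))
  expect_equal(rms_o, rms_b, tolerance = 1e-6)
})

test_that("exact linear order parameters give R = 1 and an aligned mode", {
  set.seed(12)
  X <- matrix(rnorm(200 * 24), 200)
  y <- 3 * X[, 7] + 2
  # noiseless linear response: full-rank PLS reproduces it exactly
  m <- fit_fma(X, y, n_components = 24L)
  expect_equal(m$R_valid, 1, tolerance = 1e-6)
  expect_equal(m$R_train, 1, tolerance = 1e-6)
  expect_gt(abs(m$mode[7]), 0.999)
  # independent noise: no predictive power at 500 frames
  y2 <- rnorm(500)
  m2 <- fit_fma(matrix(rnorm(500 * 30), 500), y2, n_components = 1L)
  expect_lt(abs(m2$R_valid), 0.2)
  expect_error(fit_fma(X, rep(1, 200)), "zero-variance")
  expect_error(fit_fma(X, y, n_components = 200L), "< number of frames")
})

test_that("planted modes are recovered at moderate signal-to-noise", {
  set.seed(13)
  p <- 45L; n <- 600L
  mvec <- rnorm(p); mvec <- mvec / sqrt(sum(mvec^2))
  X <- matrix(rnorm(n * p), n)
  proj <- drop(X %*% mvec)
  y <- proj + rnorm(n, sd = sd(proj) / 5)  # SNR 5
  m <- fit_fma(X, y, n_components = 3L)
  expect_gte(abs(sum(m$mode * mvec)), 0.9)
  expect_gte(m$R_valid, 0.9)
})

test_that("PLS equals the OLS oracle in the full-rank limit", {
  set.seed(14)
  X <- matrix(rnorm(50 * 6), 50)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3, -1)) + rnorm(50, sd = 0.3)
  m <- fit_fma(X, y, n_components = 6L, split = 0.5)
  train <- 1:25
  df <- data.frame(y = y[train], X[train, ])
  beta_ols <- coef(lm(y ~ ., df))[-1]
  expect_equal(unname(m$coef), unname(beta_ols), tolerance = 1e-8)
})

test_that("the mode is invariant (up to sign) to training-frame order", {
  set.seed(15)
  X <- matrix(rnorm(120 * 12), 120)
  y <- drop(X %*% rnorm(12)) + rnorm(120, sd = 0.5)
  m <- fit_fma(X, y, n_components = 2L)
  perm <- sample(1:60)
  Xp <- X; Xp[1:60, ] <- X[perm, ]
  yp <- y; yp[1:60] <- y[perm]
  mp <- fit_fma(Xp, yp, n_components = 2L)
  expect_equal(abs(sum(m$mode * mp$mode)), 1, tolerance = 1e-8)
})

test_that("predictions agree with the mixOmics PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(16)
  X <- matrix(rnorm(80 * 10), 80,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- drop(X %*% rnorm(10)) + rnorm(80, sd = 0.5)
  for (nc in c(1L, 3L)) {
    mu <- colMeans(X)
    beta <- kinkgate:::pls1_coef(sweep(X, 2L, mu), y - mean(y), nc)
    fit <- mixOmics::pls(X, y, ncomp = nc, scale = FALSE, mode = "regression")
    pred <- predict(fit, X)$predict[, 1, nc]
    ours <- drop(sweep(X, 2L, mu) %*% beta) + mean(y)
    expect_equal(unname(ours), unname(pred), tolerance = 1e-6)
  }
})

test_that("extreme conformations bracket the mean and recover templates", {
  set.seed(17)
  X <- matrix(rnorm(100 * 9), 100)
  y <- drop(X %*% rnorm(9))
  m <- fit_fma(X, y, n_components = 1L)
  ex50 <- extreme_conformations(m, c(50, 50))
  expect_equal(ex50$low, ex50$high)
  expect_equal(as.vector(t(ex50$low)),
               m$mean_structure + m$mode * median(m$projections))
  # symmetric projections -> extremes symmetric about the mean
  ex <- extreme_conformations(m, c(10, 90))
  mid <- (as.vector(t(ex$low)) + as.vector(t(ex$high))) / 2
  q <- quantile(m$projections, c(0.1, 0.9), names = FALSE)
  expect_equal(mid, m$mean_structure + m$mode * mean(q))
  # synthetic kink data: extremes reproduce the planted templates
  spec <- synthetic_spec(n_frames = 600L, seed = 5L, noise_sigma = 0.004,
                         k_kb = 0.8, k_bk = 0.8)
  gen <- generate_trajectory(spec)
  fr <- superpose(gen$frames, gen$topology, "name CA and subunit A")
  Xc <- coordinate_matrix(fr, gen$topology,
                          "subunit A and resid 71:98 and name CA")
  yb <- bending_angle(fr, gen$topology)[, "A"]
  mc <- fit_fma(Xc, yb, n_components = 1L)
  exc <- extreme_conformations(mc, c(1, 99))
  st <- gen$truth$states[, "A"]
  tmpl <- function(lab) matrix(colMeans(Xc[st == lab, ]), ncol = 3L,
                               byrow = TRUE)
  rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  expect_lt(rmsd(exc$high, tmpl("kinked")), 0.05)
  expect_lt(rmsd(exc$low, tmpl("bent")), 0.05)
})

test_that("blocked cross-validation picks the planted component count", {
  set.seed(18)
  p <- 20L; n <- 400L
  # X carries one latent direction; y follows that direction
  t_lat <- rnorm(n)
  load <- rnorm(p)
  X <- tcrossprod(t_lat, load) + matrix(rnorm(n * p, sd = 0.1), n)
  y <- t_lat + rnorm(n, sd = 0.3)
  cv <- cross_validate(X, y, component_grid = 1:4, k_folds = 5L)
  expect_equal(cv$n_components, 1L)
  expect_true(cv$reliable)
  # pure noise: flagged unreliable
  cvn <- cross_validate(X, rnorm(n), component_grid = 1:3, k_folds = 5L)
  expect_false(cvn$reliable)
  # determinism
  cv2 <- cross_validate(X, y, component_grid = 1:4, k_folds = 5L)
  expect_identical(cv, cv2)
})

test_that("the mode opens the Thr59 ring when bending decreases to bent", {
  # pipeline sign check: planted coupling makes the O-gamma ring wider in
  # bent-dominated configurations, and the FMA extremes must show it
  spec <- synthetic_spec(n_frames = 800L, seed = 21L, noise_sigma = 0.004,
                         k_kb = 0.8, k_bk = 0.8)
  gen <- generate_trajectory(spec)
  fr <- superpose(gen$frames, gen$topology, "name CA")
  X <- coordinate_matrix(fr, gen$topology, "resid 59 and name OG1")
  y <- bending_angle(fr, gen$topology)[, "A"]
  og <- cross_subunit_distance(fr, gen$topology, "resid 59 and name OG1")
  m <- fit_fma(X, y, n_components = 2L)
  ex <- extreme_conformations(m, c(5, 95))
  ring_diag <- function(pts) (sqrt(sum((pts[1, ] - pts[3, ])^2)) +
                                sqrt(sum((pts[2, ] - pts[4, ])^2))) / 2
  # low projection = low angle = bent-ward: ring must be wider
  expect_gt(ring_diag(ex$low), ring_diag(ex$high))
})
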