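# Functional mode analysis: the collective backbone motion maximally
# correlated with a scalar order parameter (here the inner-helix bending
# angle), extracted by partial-least-squares (PLS1) regression of the
# superposed coordinates against the order parameter.

# Kabsch optimal rotation R minimizing ||P R - Q|| for centred P, Q
# (both n x 3): R = U C V' from the SVD of P'Q, with C correcting an
# improper reflection.
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(tcrossprod(s$u, s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition of a trajectory
#'
#' Each frame is superposed (optimal rotation + translation, Kabsch) onto a
#' reference frame over a fit selection; the transform is applied to all
#' atoms. Removes rigid-body motion before any collective-motion analysis.
#' Note the superposed coordinates are no longer wrapped in the box.
#'
#' @inheritParams hbond_distance
#' @param fit_expression selection of atoms used for the fit (at least 3,
#'   non-collinear)
#' @param reference_frame 1-based index of the reference frame
#' @return a `frame_series` of superposed coordinates
#' @export
superpose <- function(frames, topology, fit_expression = "name CA",
                      reference_frame = 1L, config = channel_config()) {
  sel <- select(topology, fit_expression)
  if (length(sel$indices) < 3L) stop("fit selection needs at least 3 atoms")
  idx <- sel$indices + 1L
  ref <- frames$coords[idx, , reference_frame]
  refc <- sweep(ref, 2L, colMeans(ref))
  if (svd(refc)$d[2] < 1e-10)
    stop("degenerate fit: fit selection is (near-)collinear")
  out <- frames$coords
  nf <- n_frames(frames)
  for (f in seq_len(nf)) {
    P <- frames$coords[idx, , f]
    mu <- colMeans(P)
    R <- kabsch_rotation(sweep(P, 2L, mu), refc)
    all_f <- sweep(frames$coords[, , f], 2L, mu)
    out[, , f] <- sweep(all_f %*% R, 2L, colMeans(ref), "+")
  }
  frame_series(out, frames$box, frames$times)
}

#' Flatten selected coordinates to a frames x 3N matrix
#' @inheritParams hbond_distance
#' @param expression selection of the fitted atom set (default backbone)
#' @return matrix with one row per frame, columns x1,y1,z1,x2,...
#' @export
coordinate_matrix <- function(frames, topology, expression = "backbone") {
  sel <- select(topology, expression)
  if (length(sel$indices) == 0L) stop("empty selection: ", expression)
  sub <- frames$coords[sel$indices + 1L, , , drop = FALSE]
  nf <- dim(sub)[3]
  X <- t(matrix(aperm(sub, c(2L, 1L, 3L)), ncol = nf))
  attr(X, "atom_ids") <- sel$indices
  X
}

# PLS1 by NIPALS on centred X (n x p) and centred y; returns the
# regression coefficient vector for `ncomp` latent components.
pls1_coef <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  X <- Xc
  y <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("zero covariance: cannot extract component ", a)
    w <- w / nw
    t_ <- X %*% w
    tt <- sum(t_^2)
    pvec <- crossprod(X, t_) / tt
    qa <- sum(y * t_) / tt
    X <- X - tcrossprod(t_, pvec)
    y <- y - t_ * qa
    W[, a] <- w
    P[, a] <- pvec
    q[a] <- qa
  }
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a functional mode by PLS regression
#'
#' Partial-least-squares regression of superposed, centred coordinates
#' against a centred scalar order parameter, with `n_components` latent
#' vectors. The functional mode is the normalized regression coefficient
#' vector: the unit collective displacement whose amplitude best predicts
#' the order parameter. Frames are split into contiguous training and
#' validation blocks (time-correlated frames make random splits
#' over-optimistic); R_train and R_valid are the Pearson correlations
#' between predicted and actual order parameter on the two blocks.
#'
#' @param X frames x 3N coordinate matrix (from [coordinate_matrix()] on a
#'   superposed trajectory)
#' @param y per-frame order parameter (e.g. one subunit's bending angle)
#' @param n_components number of PLS components
#' @param split fraction of frames in the training block
#' @param seed retained for interface stability; the default contiguous
#'   split is deterministic and does not consume randomness
#' @return object of class `fma_model`: `mean_structure` (3N), unit `mode`
#'   (3N), `projections` of all frames onto the mode (nm), `R_train`,
#'   `R_valid`, `n_components`, `train_idx`
#' @export
fit_fma <- function(X, y, n_components = 1L, split = 0.5, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  stop_if_not_finite(y, "y")
  if (stats::var(y) == 0) stop("zero-variance order parameter")
  n <- nrow(X)
  if (n_components >= n) stop("n_components must be < number of frames")
  n_train <- max(2L, floor(n * split))
  if (n - n_train < 2L) stop("validation block too small; lower `split`")
  train <- seq_len(n_train)
  valid <- setdiff(seq_len(n), train)
  mu <- colMeans(X[train, , drop = FALSE])
  ybar <- mean(y[train])
  Xc <- sweep(X, 2L, mu)
  beta <- pls1_coef(Xc[train, , drop = FALSE], y[train] - ybar, n_components)
  pred <- drop(Xc %*% beta) + ybar
  mode <- beta / sqrt(sum(beta^2))
  structure(list(mean_structure = mu, mode = mode,
                 projections = drop(Xc %*% mode),
                 coef = beta, intercept = ybar,
                 R_train = stats::cor(pred[train], y[train]),
                 R_valid = stats::cor(pred[valid], y[valid]),
                 n_components = n_components, train_idx = train),
            class = "fma_model")
}

#' @export
print.fma_model <- function(x, ...) {
  cat(sprintf("<fma_model> %d components, R_train = %.3f, R_valid = %.3f\n",
              x$n_components, x$R_train, x$R_valid))
  invisible(x)
}

#' Extreme conformations along the functional mode
#'
#' The mean structure displaced along the mode to the low and high
#' percentiles of the observed projections; on kink-gating data these are
#' the kinked-like and bent-like end states of the collective motion.
#'
#' @param model a fitted `fma_model`
#' @param percentiles length-2 percentile pair of the projection
#'   distribution
#' @return list with `low` and `high` coordinate matrices (n_atoms x 3)
#'   and the projection values used
#' @export
extreme_conformations <- function(model, percentiles = c(1, 99)) {
  if (is.null(model$projections)) stop("model is not fitted")
  qs <- stats::quantile(model$projections, percentiles / 100, names = FALSE)
  shape <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  list(low = shape(model$mean_structure + model$mode * qs[1]),
       high = shape(model$mean_structure + model$mode * qs[2]),
       projections = qs)
}

#' Write an extreme-conformation pair as a two-model PDB
#'
#' @param extremes result of [extreme_conformations()]
#' @param topology topology restricted to the fitted atom set
#' @param atom_ids 0-based ids of the fitted atoms (e.g.
#'   `attr(X, "atom_ids")`)
#' @param path output PDB
#' @param box length-3 box (nm) written to CRYST1
#' @return `path`, invisibly
#' @export
write_extremes <- function(extremes, topology, atom_ids, path,
                           box = c(10, 10, 10)) {
  atoms <- topology$atoms[match(atom_ids, topology$atoms$atom_id), ]
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  sub <- new_topology(atoms)
  coords <- array(c(extremes$low, extremes$high),
                  dim = c(nrow(atoms), 3L, 2L))
  write_frames(frame_series(coords, box), sub, path, format = "pdb")
}

#' Choose the PLS component count by blocked cross-validation
#'
#' Contiguous folds (time-aware), mean and SEM of the validation
#' correlation per component count, and the one-standard-error rule: the
#' smallest count within 1 SEM of the best mean. A selection with best
#' R_valid below 0.5 is flagged unreliable.
#'
#' @param X frames x 3N coordinate matrix
#' @param y per-frame order parameter
#' @param component_grid candidate component counts
#' @param k_folds number of contiguous folds (>= 2)
#' @param seed retained for interface stability (folds are deterministic)
#' @return list: `n_components`, `mean_R`, `sem_R` (per grid entry),
#'   `reliable`
#' @export
cross_validate <- function(X, y, component_grid = 1:5, k_folds = 5L,
                           seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (n < 2L * k_folds) stop("too few frames for ", k_folds, " folds")
  fold <- cut(seq_len(n), k_folds, labels = FALSE)
  res <- matrix(NA_real_, length(component_grid), k_folds)
  for (ci in seq_along(component_grid)) {
    nc <- component_grid[ci]
    for (k in seq_len(k_folds)) {
      test <- which(fold == k)
      train <- setdiff(seq_len(n), test)
      if (nc >= length(train)) next
      mu <- colMeans(X[train, , drop = FALSE])
      ybar <- mean(y[train])
      beta <- tryCatch(
        pls1_coef(sweep(X[train, , drop = FALSE], 2L, mu), y[train] - ybar, nc),
        error = function(e) NULL)
      if (is.null(beta)) next
      pred <- drop(sweep(X[test, , drop = FALSE], 2L, mu) %*% beta) + ybar
      res[ci, k] <- stats::cor(pred, y[test])
    }
  }
  mean_R <- rowMeans(res, na.rm = TRUE)
  sem_R <- apply(res, 1L, sem)
  best <- which.max(mean_R)
  thr <- mean_R[best] - ifelse(is.na(sem_R[best]), 0, sem_R[best])
  chosen <- component_grid[min(which(mean_R >= thr))]
  list(n_components = chosen, component_grid = component_grid,
       mean_R = mean_R, sem_R = sem_R, per_fold = res,
       reliable = mean_R[best] >= 0.5)
}
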