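#' Time-bin indices of a trial window
#'
#' Resolves a window specification against an activity tensor's epoch
#' labels. `epochs` selects whole epochs; `shift_start` / `shift_end`
#' move the window boundaries inward by a number of milliseconds (e.g. the
#' combined cue-delay window is `epochs = c("cue", "delay")`,
#' `shift_start = 100`, `shift_end = 200`).
#'
#' @param act an `activity_tensor` (or anything with `epoch` and `dt`).
#' @param epochs character vector of epoch names, in trial order.
#' @param shift_start ms trimmed from the window start.
#' @param shift_end ms trimmed from the window end.
#' @return integer vector of time-bin indices.
#' @export
window_bins <- function(act, epochs, shift_start = 0, shift_end = 0) {
  sel <- which(act$epoch %in% epochs)
  if (length(sel) == 0) stop("epoch(s) not present: ",
                             paste(epochs, collapse = ", "))
  drop_s <- shift_start / act$dt
  drop_e <- shift_end / act$dt
  if (drop_s %% 1 != 0 || drop_e %% 1 != 0) {
    stop("window shifts must be multiples of dt")
  }
  if (drop_s + drop_e >= length(sel)) stop("window shifts leave no bins")
  sel[seq.int(1 + drop_s, length(sel) - drop_e)]
}

#' Epoch-restricted population matrix
#'
#' Arranges condition-averaged rates into the N x (C*T) matrix used for
#' epoch-wise PCA: rows are units, columns are condition-major
#' (condition 1 bins, then condition 2 bins, ...) over the selected window.
#'
#' @param act an `activity_tensor` from [condition_activity()].
#' @param epochs,shift_start,shift_end window specification
#'   (see [window_bins()]); alternatively pass explicit `bins`.
#' @param context optional `"color"` or `"motion"` to restrict conditions.
#' @param bins explicit time-bin indices overriding the epoch window.
#' @return N x (C*T) matrix with attributes `conditions` and `bins`.
#' @export
epoch_matrix <- function(act, epochs = NULL, shift_start = 0, shift_end = 0,
                         context = NULL, bins = NULL) {
  if (is.null(bins)) {
    if (is.null(epochs)) stop("give either epochs or bins")
    bins <- window_bins(act, epochs, shift_start, shift_end)
  }
  conds <- seq_len(nrow(act$conditions))
  if (!is.null(context)) {
    conds <- which(act$conditions$context == context)
    if (length(conds) == 0) stop("no conditions for context ", context)
  }
  blocks <- lapply(conds, function(ci) act$rates[, ci, bins, drop = TRUE])
  X <- do.call(cbind, blocks)
  attr(X, "conditions") <- conds
  attr(X, "bins") <- bins
  X
}

#' Fit a principal-component subspace
#'
#' PCA on an N x M population matrix: rows (units) are centered by their
#' mean over columns, and the leading `k` principal axes are returned with
#' their explained-variance ratios.
#'
#' @param X population matrix (units x samples), e.g. [epoch_matrix()].
#' @param k subspace dimension.
#' @return object of class `subspace`: `basis` (N x k, orthonormal),
#'   `evr` (explained-variance ratios of the first k PCs), `center`
#'   (unit means), `sdev` (all singular values / sqrt(M - 1)).
#' @export
fit_subspace <- function(X, k = 2) {
  if (!all(is.finite(X))) stop("X must be finite")
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  tot <- sum(Xc^2)
  if (tot == 0) stop("X has zero variance")
  pc <- prcomp(t(Xc), center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(basis = pc$rotation[, seq_len(k), drop = FALSE],
                 evr = evr[seq_len(k)], center = ctr, sdev = pc$sdev),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("subspace: %d units, k = %d, explained variance %s (cum %.1f%%)\n",
              nrow(x$basis), ncol(x$basis),
              paste(sprintf("%.1f%%", 100 * x$evr), collapse = " + "),
              100 * sum(x$evr)))
  invisible(x)
}

#' Cumulative percent variance explained
#'
#' Convenience wrapper: percent of total variance captured by the first
#' `k` principal components of a population matrix.
#'
#' @param X population matrix (units x samples).
#' @param k number of leading components.
#' @return percentage in \[0, 100\].
#' @export
explained_variance_pct <- function(X, k) {
  s <- fit_subspace(X, k = min(k, min(dim(X)) - 1L))
  100 * sum(s$evr[seq_len(k)])
}

#' Define a task-related axis
#'
#' A task axis is the first principal component of a context-restricted,
#' epoch-restricted population matrix: the C-cue- and M-cue-axes come from
#' the cue epoch of color- and motion-context conditions, the C-choice- and
#' M-choice-axes from the sensory-stimulus (integration) epoch. The sign is
#' fixed so that the mean projection of the window's second half is
#' positive.
#'
#' @param act an `activity_tensor`.
#' @param name one of `"C-cue"`, `"M-cue"`, `"C-choice"`, `"M-choice"`.
#' @return object of class `task_axis`: unit `vector`, `name`, `evr1`
#'   (variance ratio of the defining PC), `center`.
#' @export
define_task_axis <- function(act, name = c("C-cue", "M-cue",
                                           "C-choice", "M-choice")) {
  name <- match.arg(name)
  context <- if (grepl("^C", name)) "color" else "motion"
  epoch <- if (grepl("cue", name)) "cue" else "stim"
  X <- epoch_matrix(act, epochs = epoch, context = context)
  sub <- fit_subspace(X, k = 1)
  v <- sub$basis[, 1]
  # sign convention: positive mean projection of late-window states
  late <- X[, seq.int(ncol(X) %/% 2 + 1, ncol(X)), drop = FALSE] - sub$center
  if (mean(crossprod(late, v)) < 0) v <- -v
  structure(list(vector = v, name = name, evr1 = sub$evr[1],
                 center = sub$center),
            class = "task_axis")
}

#' @export
print.task_axis <- function(x, ...) {
  cat(sprintf("task_axis %s: %d units, defining PC explains %.1f%%\n",
              x$name, length(x$vector), 100 * x$evr1))
  invisible(x)
}

as_axis_vector <- function(a) {
  v <- if (inherits(a, "task_axis")) a$vector else as.numeric(a)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero axis vector")
  v / n
}

#' Angle between an axis and a subspace
#'
#' `arccos` of the norm of the axis's orthogonal projection onto the
#' subspace: 0 degrees if the axis lies in the span, 90 if orthogonal.
#' Axes/planes at more than 70 degrees are conventionally called nearly
#' orthogonal, below 20 degrees nearly parallel.
#'
#' @param axis a `task_axis` or numeric vector.
#' @param subspace a `subspace` (or N x k orthonormal basis matrix).
#' @return angle in degrees, in \[0, 90\].
#' @export
axis_subspace_angle <- function(axis, subspace) {
  v <- as_axis_vector(axis)
  B <- if (inherits(subspace, "subspace")) subspace$basis else subspace
  p <- B %*% crossprod(B, v)
  acos(min(1, sqrt(sum(p^2)))) * 180 / pi
}

#' Angle between two axes
#'
#' Unsigned (default): `arccos(|a . b|)` in \[0, 90\] degrees, direction-
#' agnostic. Signed: `arccos(a . b)` in \[0, 180\], used e.g. to test
#' whether two axes project onto a component in opposite directions.
#'
#' @param a,b `task_axis` objects or numeric vectors.
#' @param signed logical.
#' @return angle in degrees.
#' @export
axis_axis_angle <- function(a, b, signed = FALSE) {
  va <- as_axis_vector(a)
  vb <- as_axis_vector(b)
  d <- max(-1, min(1, sum(va * vb)))
  if (signed) acos(d) * 180 / pi else acos(abs(d)) * 180 / pi
}

#' Project a trajectory onto a subspace
#'
#' Centers states with the subspace's stored unit means and projects onto
#' its leading `dims` axes.
#'
#' @param traj T x N matrix of states (or N-vector).
#' @param subspace a `subspace`.
#' @param dims number of leading subspace dimensions.
#' @return T x dims matrix of projected coordinates.
#' @export
project_trajectory <- function(traj, subspace, dims = ncol(subspace$basis)) {
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1)
  B <- subspace$basis[, seq_len(dims), drop = FALSE]
  (traj - rep(subspace$center, each = nrow(traj))) %*% B
}

#' Distance between two projected trajectories
#'
#' Euclidean distance at each time point between two equal-length
#' trajectories, in the leading `dims` dimensions of a common subspace.
#'
#' @param trajA,trajB T x N state matrices.
#' @param subspace common `subspace` for the projection.
#' @param dims projection dimension (default 3).
#' @return numeric vector of per-time distances.
#' @export
trajectory_distance <- function(trajA, trajB, subspace, dims = 3) {
  if (nrow(trajA) != nrow(trajB)) stop("trajectory lengths differ")
  pa <- project_trajectory(trajA, subspace, dims)
  pb <- project_trajectory(trajB, subspace, dims)
  sqrt(rowSums((pa - pb)^2))
}

#' Trajectory velocity
#'
#' Speed of a (projected) trajectory: `v(t) = dist(P_t, P_{t+n}) / n`,
#' the displacement over an `n`-step look-ahead divided by `n`. The result
#' is `n` samples shorter than the input.
#'
#' @param traj T x d matrix of trajectory points.
#' @param n look-ahead in steps (>= 1).
#' @return numeric vector of length `T - n`.
#' @export
trajectory_velocity <- function(traj, n = 1) {
  if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
  nt <- nrow(traj)
  if (n < 1) stop("n must be at least 1")
  if (n >= nt) stop("n must be smaller than the trajectory length")
  idx <- seq_len(nt - n)
  sqrt(rowSums((traj[idx + n, , drop = FALSE] -
                  traj[idx, , drop = FALSE])^2)) / n
}

#' Network energy over time
#'
#' Mean firing rate over the activated-unit subset at each time bin,
#' averaged across conditions. Activated units default to
#' [active_units()] of the tensor.
#'
#' @param act an `activity_tensor`.
#' @param units indices of activated units; default from [active_units()].
#' @param threshold activation threshold passed through to
#'   [active_units()].
#' @return numeric vector, one energy value per time bin.
#' @export
network_energy <- function(act, units = NULL, threshold = 5) {
  if (is.null(units)) units <- active_units(act, threshold = threshold)
  if (length(units) == 0) stop("no active units")
  apply(act$rates[units, , , drop = FALSE], 3, mean)
}

#' Correlation of population activity between task periods
#'
#' Pearson correlation between the epoch-mean population vectors of the
#' four single epochs (cue, delay, stim, resp) and the two cross-epoch
#' windows (cue-delay, integ-resp). A constant population vector has no
#' defined correlation; those entries are returned as NA with a warning.
#'
#' @param act an `activity_tensor`.
#' @param periods named list of time-bin index vectors; defaults to the
#'   six standard periods.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
epoch_correlation <- function(act, periods = NULL) {
  if (is.null(periods)) {
    periods <- list(
      cue = window_bins(act, "cue"),
      delay = window_bins(act, "delay"),
      integ = window_bins(act, "stim"),
      resp = window_bins(act, "resp"),
      cue_delay = window_bins(act, c("cue", "delay"),
                              shift_start = 100, shift_end = 200),
      integ_resp = window_bins(act, c("stim", "resp"), shift_start = 500))
  }
  vecs <- vapply(periods,
                 function(bins) apply(act$rates[, , bins, drop = FALSE],
                                      1, mean),
                 numeric(dim(act$rates)[1]))
  sds <- apply(vecs, 2, sd)
  if (any(sds == 0)) {
    warning("constant population vector in period(s): ",
            paste(names(periods)[sds == 0], collapse = ", "))
  }
  cm <- suppressWarnings(cor(vecs))
  diag(cm) <- 1
  cm
}

#' Choose the choice-parallel plane of the integration subspace
#'
#' Among candidate principal-component pairs of the sensory-stimulus epoch
#' subspace, selects the plane with the smallest mean angle to the two
#' choice axes — the plane the choice axes are parallel to. With
#' well-separated context (PC1) and choice structure this picks (PC2, PC3).
#'
#' @param subspace3 `subspace` with at least 3 components (stimulus epoch).
#' @param c_choice,m_choice the two choice axes.
#' @param candidates list of index pairs to consider.
#' @return list with `pair` (chosen indices), `basis` (N x 2), and the
#'   per-candidate mean angles.
#' @export
select_integ_plane <- function(subspace3, c_choice, m_choice,
                               candidates = list(c(1, 2), c(1, 3), c(2, 3))) {
  angles <- vapply(candidates, function(pr) {
    B <- subspace3$basis[, pr, drop = FALSE]
    mean(c(axis_subspace_angle(c_choice, B),
           axis_subspace_angle(m_choice, B)))
  }, numeric(1))
  best <- which.min(angles)
  list(pair = candidates[[best]],
       basis = subspace3$basis[, candidates[[best]], drop = FALSE],
       mean_angles = setNames(angles, vapply(candidates, paste,
                                             character(1), collapse = ",")))
}
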