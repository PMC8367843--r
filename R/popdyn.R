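# rates_matrix: accept an activity_tensor (condition-averaged over a
# window, mean across conditions) or a plain units x time matrix.
delay_rates <- function(x, epochs = "delay", conditions = NULL) {
  if (inherits(x, "activity_tensor")) {
    bins <- window_bins(x, epochs)
    conds <- if (is.null(conditions)) seq_len(dim(x$rates)[2]) else conditions
    apply(x$rates[, conds, bins, drop = FALSE], c(1, 3), mean)
  } else {
    as.matrix(x)
  }
}

#' Sort units by peak time
#'
#' Normalizes each unit's activity to its own peak and orders units by the
#' time bin of that peak (ties broken by unit index). All-zero rows carry
#' no peak and are dropped with a warning.
#'
#' @param rates units x time matrix (e.g. condition-averaged delay
#'   activity), or an `activity_tensor` (delay epoch, mean over
#'   conditions).
#' @param epochs epoch window when `rates` is an `activity_tensor`.
#' @return list with `order` (unit indices sorted by peak time),
#'   `peak_time` (per retained unit), `heatmap` (normalized and sorted
#'   matrix), `excluded` (dropped unit indices).
#' @export
peak_sort <- function(rates, epochs = "delay") {
  R <- delay_rates(rates, epochs)
  mx <- apply(R, 1, max)
  excluded <- which(mx == 0)
  if (length(excluded) > 0) {
    warning(length(excluded), " all-zero unit(s) excluded from peak sort")
  }
  keep <- setdiff(seq_len(nrow(R)), excluded)
  Rk <- R[keep, , drop = FALSE] / mx[keep]
  pk <- apply(Rk, 1, which.max)
  ord <- keep[order(pk, keep)]
  list(order = ord, peak_time = pk[order(pk, keep)],
       heatmap = Rk[order(pk, keep), , drop = FALSE], excluded = excluded)
}

#' Sequentiality index
#'
#' `SI = H(peak times) + mean_i log(ridge_i / background_i)`: the entropy
#' (natural log) of the distribution of units' peak response times plus the
#' mean log ridge-to-background ratio, where a unit's ridge is its mean
#' activity inside a window of `ridge_window` bins centered on its peak
#' and the background is its mean activity outside that window. High SI
#' means units tile the epoch with sharp, evenly spread peaks. Units with
#' zero background are excluded from the ridge term (with a message); the
#' entropy term uses all peaked units.
#'
#' @param rates units x time matrix or `activity_tensor`.
#' @param ridge_window ridge window width in bins; default 1/8 of the
#'   epoch length (minimum 1).
#' @param n_entropy_bins number of histogram bins for peak times; default
#'   one per time bin.
#' @param epochs epoch window when `rates` is an `activity_tensor`.
#' @return object of class `seq_stats`: `si`, `entropy`, `mean_log_ridge`,
#'   `peak_time`, `order`, `n_units`.
#' @export
sequentiality_index <- function(rates, ridge_window = NULL,
                                n_entropy_bins = NULL, epochs = "delay") {
  R <- delay_rates(rates, epochs)
  nt <- ncol(R)
  if (is.null(ridge_window)) ridge_window <- max(1, nt %/% 8)
  if (ridge_window >= nt) stop("ridge_window must be smaller than the epoch")
  if (is.null(n_entropy_bins)) n_entropy_bins <- nt
  mx <- apply(R, 1, max)
  keep <- which(mx > 0)
  if (length(keep) == 0) stop("no unit with positive activity")
  R <- R[keep, , drop = FALSE]
  pk <- apply(R, 1, which.max)
  # entropy of the peak-time distribution
  bins <- cut(pk, breaks = seq(0.5, nt + 0.5,
                               length.out = n_entropy_bins + 1),
              labels = FALSE)
  p <- tabulate(bins, nbins = n_entropy_bins) / length(bins)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  # ridge-to-background per unit
  half <- ridge_window / 2
  logratio <- vapply(seq_len(nrow(R)), function(i) {
    lo <- max(1, ceiling(pk[i] - half))
    hi <- min(nt, floor(pk[i] + half))
    inside <- seq.int(lo, hi)
    outside <- setdiff(seq_len(nt), inside)
    bg <- mean(R[i, outside])
    if (bg == 0) return(NA_real_)
    log(mean(R[i, inside]) / bg)
  }, numeric(1))
  n_bg0 <- sum(is.na(logratio))
  if (n_bg0 > 0) {
    message(n_bg0, " unit(s) with zero background excluded from ridge term")
  }
  structure(list(si = entropy + mean(logratio, na.rm = TRUE),
                 entropy = entropy,
                 mean_log_ridge = mean(logratio, na.rm = TRUE),
                 peak_time = pk, order = keep[order(pk, keep)],
                 n_units = length(keep)),
            class = "seq_stats")
}

#' @export
print.seq_stats <- function(x, ...) {
  cat(sprintf("seq_stats: SI = %.3f (entropy %.3f + mean log ridge %.3f), %d units\n",
              x$si, x$entropy, x$mean_log_ridge, x$n_units))
  invisible(x)
}

#' Monte Carlo distribution of the sequentiality index
#'
#' Distribution of SI over repeated random subsamples of units, following
#' the Monte Carlo control used to compare trained and untrained networks
#' (compare two distributions with [stats::ks.test()]).
#'
#' @param rates units x time matrix or `activity_tensor`.
#' @param n_samples number of Monte Carlo draws.
#' @param subsample units drawn (with replacement) per sample.
#' @param ... passed to [sequentiality_index()].
#' @return numeric vector of `n_samples` SI values.
#' @export
si_monte_carlo <- function(rates, n_samples = 10000, subsample = 128, ...) {
  if (n_samples < 100) {
    warning("n_samples < 100 gives a very coarse SI distribution")
  }
  R <- delay_rates(rates, ...)
  ok <- which(apply(R, 1, max) > 0)
  vapply(seq_len(n_samples), function(i) {
    idx <- sample(ok, subsample, replace = TRUE)
    suppressMessages(sequentiality_index(R[idx, , drop = FALSE]))$si
  }, numeric(1))
}

#' Recurrent weight vs. peak-order offset
#'
#' Mean and standard deviation of recurrent weights `W[post, pre]` as a
#' function of the peak-order difference between the presynaptic and
#' postsynaptic units. A positive offset is a "forward" connection (from
#' an earlier-peaking to a later-peaking unit). The asymmetry statistic is
#' the mean forward weight minus the mean backward weight; a positive
#' value indicates the forward-biased connectivity that supports
#' sequential activation.
#'
#' @param W_rec N x N recurrent weight matrix (`W[post, pre]`).
#' @param order unit indices sorted by peak time (from [peak_sort()]);
#'   units not listed are ignored.
#' @return list with `profile` (data.frame offset, mean, sd, n),
#'   `asymmetry`.
#' @export
weight_order_profile <- function(W_rec, order) {
  n <- length(order)
  if (n < 2) stop("order must contain at least two units")
  W <- W_rec[order, order]
  pos_post <- row(W)
  pos_pre <- col(W)
  off <- pos_post - pos_pre          # positive: pre peaks earlier
  keep <- off != 0                   # drop self-connections
  offs <- seq.int(-(n - 1), n - 1)
  offs <- offs[offs != 0]
  stats <- t(vapply(offs, function(d) {
    w <- W[keep & off == d]
    c(mean = mean(w), sd = if (length(w) > 1) sd(w) else NA_real_,
      n = length(w))
  }, numeric(3)))
  profile <- data.frame(offset = offs, mean = stats[, 1], sd = stats[, 2],
                        n = stats[, 3])
  asym <- mean(W[keep & off > 0]) - mean(W[keep & off < 0])
  list(profile = profile, asymmetry = asym)
}

# closed-form least-squares skew-symmetric fit of Y ~ M X:
# minimize ||Y - M X||_F^2 over skew M, by solving the normal equations in
# the k(k-1)/2 dimensional basis of elementary skew matrices.
skew_lsq <- function(X, Y) {
  k <- nrow(X)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  np <- nrow(pairs)
  S <- tcrossprod(X)              # X X^T
  C <- tcrossprod(Y, X)           # Y X^T
  G <- matrix(0, np, np)
  h <- numeric(np)
  for (a in seq_len(np)) {
    ia <- pairs[a, 1]; ja <- pairs[a, 2]
    # tr(B_a S B_b^T) with B = E_ij - E_ji
    for (b in seq_len(np)) {
      ib <- pairs[b, 1]; jb <- pairs[b, 2]
      G[a, b] <- (ia == ib) * S[ja, jb] - (ia == jb) * S[ja, ib] -
        (ja == ib) * S[ia, jb] + (ja == jb) * S[ia, ib]
    }
    h[a] <- C[ia, ja] - C[ja, ia]
  }
  cc <- tryCatch(solve(G, h), error = function(e) {
    # rank-deficient data (e.g. motionless directions): minimum-norm
    # least-squares coefficients via the pseudo-inverse
    sv <- svd(G)
    pos <- sv$d > 1e-12 * max(sv$d, 1e-300)
    if (!any(pos)) return(rep(0, length(h)))
    sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], h) / sv$d[pos])
  })
  M <- matrix(0, k, k)
  for (a in seq_len(np)) {
    M[pairs[a, 1], pairs[a, 2]] <- cc[a]
    M[pairs[a, 2], pairs[a, 1]] <- -cc[a]
  }
  M
}

#' Fit rotational (jPCA-style) dynamics
#'
#' Reduces condition-wise trajectories to their top `k` principal
#' components (after subtracting the cross-condition mean trajectory),
#' then fits the linearized dynamics two ways: (1) a least-squares
#' skew-symmetric generator `M` of `x_dot = M x` (first-difference
#' derivative), whose purely imaginary eigenvalue pairs define rotation
#' planes `u1 = v + conj(v)`, `u2 = i (v - conj(v))`; and (2) the
#' orthogonal one-step map `Q` of the vector-autoregressive form
#' `x_{t+1} = Q x_t`, obtained as the orthogonal polar factor of the
#' unconstrained least-squares map `A = (X_{t+1} X_t')(X_t X_t')^{-1}`.
#'
#' @param act an `activity_tensor`, or a list of T x N trajectory
#'   matrices (one per condition).
#' @param k number of principal components retained (default 6).
#' @param epochs epoch window when `act` is an `activity_tensor`.
#' @param ridge small ridge added to `X_t X_t'` only if it is singular.
#' @return object of class `rotation_fit`: `M` (skew generator), `A`
#'   (unconstrained map), `Q` (orthogonal map), `P` (symmetric polar
#'   factor), `planes` (list of orthonormalized k x 2 plane bases in PC
#'   coordinates, by descending rotation frequency), `frequencies`
#'   (|imaginary eigenvalue| per plane, rad per step), `r2_M`, `r2_A`
#'   (fit quality), `proj` (list of reduced T x k trajectories), `basis`
#'   (N x k PCA basis), `center`.
#' @export
fit_rotation <- function(act, k = 6, epochs = "delay", ridge = 1e-10) {
  if (inherits(act, "activity_tensor")) {
    bins <- window_bins(act, epochs)
    trajs <- lapply(seq_len(dim(act$rates)[2]),
                    function(ci) t(act$rates[, ci, bins]))
  } else {
    trajs <- lapply(act, as.matrix)
  }
  C <- length(trajs)
  nt <- nrow(trajs[[1]])
  # subtract the cross-condition mean trajectory (the condition-
  # independent signal); with a single condition there is nothing to
  # separate and the data are used as-is
  if (C > 1) {
    cmean <- Reduce(`+`, trajs) / C
    trajs <- lapply(trajs, function(tr) tr - cmean)
  }
  stacked <- do.call(rbind, trajs)
  ctr <- colMeans(stacked)
  pc <- prcomp(stacked, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  basis <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- lapply(trajs, function(tr) {
    (tr - rep(ctr, each = nt)) %*% basis
  })
  Xt <- do.call(cbind, lapply(proj, function(p) t(p[-nt, , drop = FALSE])))
  Xt1 <- do.call(cbind, lapply(proj, function(p) t(p[-1, , drop = FALSE])))
  dX <- Xt1 - Xt
  S <- tcrossprod(Xt)
  if (rcond(S) < 1e-12) {
    warning("singular X_t X_t'; ridge-regularizing")
    S <- S + diag(max(ridge, 1e-8 * mean(diag(S))), k)
  }
  A <- tcrossprod(Xt1, Xt) %*% solve(S)
  sv <- svd(A)
  Q <- sv$u %*% t(sv$v)
  P <- sv$v %*% diag(sv$d, k) %*% t(sv$v)
  M <- skew_lsq(Xt, dX)
  eg <- eigen(M)
  im <- Im(eg$values)
  ordp <- order(-abs(im))
  planes <- list()
  freqs <- numeric(0)
  seen <- rep(FALSE, k)
  for (i in ordp) {
    if (seen[i] || abs(im[i]) < 1e-12) next
    conj_i <- which(!seen & abs(Im(eg$values) + im[i]) < 1e-10 &
                      seq_len(k) != i)[1]
    v <- eg$vectors[, i]
    u1 <- Re(v + Conj(v))
    u2 <- Re(1i * (v - Conj(v)))
    B <- qr.Q(qr(cbind(u1, u2)))
    planes[[length(planes) + 1]] <- B
    freqs <- c(freqs, abs(im[i]))
    seen[i] <- TRUE
    if (!is.na(conj_i)) seen[conj_i] <- TRUE
  }
  r2 <- function(pred) 1 - sum((dX - pred)^2) / sum(dX^2)
  structure(list(M = M, A = A, Q = Q, P = P, planes = planes,
                 frequencies = freqs, r2_M = r2(M %*% Xt),
                 r2_A = r2(A %*% Xt - Xt),
                 proj = proj, basis = basis, center = ctr),
            class = "rotation_fit")
}

#' @export
print.rotation_fit <- function(x, ...) {
  cat(sprintf(
    "rotation_fit: k = %d, %d rotation planes, freq (rad/step) %s, R2(M) = %.3f\n",
    nrow(x$M), length(x$planes),
    paste(sprintf("%.3f", x$frequencies), collapse = ", "), x$r2_M))
  invisible(x)
}

#' Project trajectories onto a rotation plane
#'
#' @param fit a [fit_rotation()] result.
#' @param plane plane index (1 = fastest rotation).
#' @param trajs optional list of T x N trajectories to reduce and project;
#'   defaults to the trajectories the fit was built from.
#' @return list of T x 2 matrices, one per condition.
#' @export
project_rotations <- function(fit, plane = 1, trajs = NULL) {
  if (plane < 1 || plane > length(fit$planes)) {
    stop("plane index out of range")
  }
  B <- fit$planes[[plane]]
  proj <- if (is.null(trajs)) fit$proj else {
    lapply(trajs, function(tr) {
      (as.matrix(tr) - rep(fit$center, each = nrow(tr))) %*% fit$basis
    })
  }
  lapply(proj, function(p) p %*% B)
}
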