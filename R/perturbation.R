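#' Scale recurrent weights globally or during the delay only
#'
#' Weight perturbation experiment: multiply `W_rec` by a scale factor
#' either across the whole trial (`mode = "global"`) or only at
#' delay-epoch timesteps (`mode = "delay_local"`). The input `params` are
#' never modified; the function returns a perturbed parameter set (global)
#' or a simulator closure (delay-local), plus a `simulate` function with
#' the same signature as [simulate_trial()] for either mode.
#'
#' @param params trained [rnn_params()].
#' @param scale multiplicative factor (> 0).
#' @param mode `"global"` or `"delay_local"`.
#' @return list with `mode`, `scale`, `params` (perturbed copy; global
#'   mode only) and `simulate(trial, noise, x0)`.
#' @export
scale_weights <- function(params, scale, mode = c("global", "delay_local")) {
  mode <- match.arg(mode)
  if (scale <= 0) stop("scale must be positive")
  if (mode == "global") {
    p2 <- params
    p2$W_rec <- params$W_rec * scale
    return(list(mode = mode, scale = scale, params = p2,
                simulate = function(trial, noise = TRUE, x0 = NULL) {
                  simulate_trial(p2, trial, noise = noise, x0 = x0)
                }))
  }
  sim_local <- function(trial, noise = TRUE, x0 = NULL) {
    u <- t(trial$u)
    nt <- ncol(u)
    in_delay <- trial$epoch == "delay"
    p2 <- params
    p2$W_rec <- params$W_rec * scale
    x <- if (is.null(x0)) rep(0, params$N) else as.numeric(x0)
    r <- softplus(x)
    X <- matrix(0, nt, params$N)
    R <- matrix(0, nt, params$N)
    Z <- matrix(0, nt, 4)
    for (t in seq_len(nt)) {
      p_t <- if (in_delay[t]) p2 else params
      st <- rnn_step(x, r, u[, t], p_t, noise = noise)
      x <- st$x
      r <- st$r
      X[t, ] <- x
      R[t, ] <- r
      Z[t, ] <- params$W_out %*% r + params$b_out
    }
    list(x = X, r = R, z = Z, epoch = trial$epoch)
  }
  list(mode = mode, scale = scale, simulate = sim_local)
}

#' Sparsify recurrent weights by magnitude
#'
#' Zeroes the smallest-magnitude off-diagonal recurrent weights until the
#' requested proportion of off-diagonal entries is zero. Self-connections
#' are preserved.
#'
#' @param params [rnn_params()].
#' @param proportion fraction of off-diagonal entries to zero, in \[0, 1).
#' @return perturbed copy of `params`.
#' @export
sparsify <- function(params, proportion) {
  if (proportion < 0 || proportion >= 1) stop("proportion must be in [0, 1)")
  p2 <- params
  if (proportion == 0) return(p2)
  W <- params$W_rec
  off <- which(row(W) != col(W))
  n_zero <- ceiling(proportion * length(off))
  drop <- off[order(abs(W[off]))[seq_len(n_zero)]]
  W[drop] <- 0
  p2$W_rec <- W
  p2
}

#' Self-connection statistics
#'
#' Summary of the recurrent matrix's diagonal (self-connections) against
#' its off-diagonal entries. `ratio` is `mean|diag| / mean|offdiag|`; if
#' every off-diagonal entry is zero the ratio is infinite and flagged.
#'
#' @param W_rec square recurrent weight matrix.
#' @return list with `diag_mean`, `diag_sd`, `offdiag_mean`, `offdiag_sd`,
#'   `ratio`, `offdiag_all_zero`.
#' @export
self_connection_stats <- function(W_rec) {
  if (nrow(W_rec) != ncol(W_rec)) stop("W_rec must be square")
  d <- diag(W_rec)
  o <- W_rec[row(W_rec) != col(W_rec)]
  mo <- mean(abs(o))
  list(diag_mean = mean(d), diag_sd = sd(d),
       offdiag_mean = mean(o), offdiag_sd = sd(o),
       ratio = if (mo == 0) Inf else mean(abs(d)) / mo,
       offdiag_all_zero = mo == 0)
}

#' Geometry of perturbed trajectories in the baseline subspace
#'
#' Simulates the 16 canonical conditions under a weight perturbation,
#' projects the perturbed condition-averaged trajectories into a subspace
#' fitted on the unperturbed network, and reports the per-condition
#' displacement plus whether the ordering of conditions by signed relevant
#' coherence (along the choice-axis direction at the end of the stimulus
#' epoch) is preserved within each context.
#'
#' @param params baseline trained [rnn_params()].
#' @param scale,mode perturbation (see [scale_weights()]).
#' @param subspace baseline `subspace`; default: 3-PC subspace of the
#'   stimulus epoch.
#' @param dims projection dimension.
#' @return list with `displacement` (data.frame per condition),
#'   `ordering_preserved` (named per context), `n_violations`.
#' @export
perturbed_geometry <- function(params, scale, mode = "global",
                               subspace = NULL, dims = 3) {
  base_act <- condition_activity(params, noise = FALSE)
  if (is.null(subspace)) {
    subspace <- fit_subspace(epoch_matrix(base_act, epochs = "stim"),
                             k = dims)
  }
  pert <- scale_weights(params, scale, mode)
  p_sim <- if (mode == "global") pert$params else NULL
  pert_act <- if (mode == "global") {
    condition_activity(p_sim, noise = FALSE)
  } else {
    # delay-local: rebuild condition averages with the stage-wise simulator
    act <- base_act
    conds <- act$conditions
    for (ci in seq_len(nrow(conds))) {
      reps <- lapply(coherence_set, function(irr) {
        spec <- trial_spec(conds$context[ci],
                           c_color = if (conds$context[ci] == "color")
                             conds$coherence[ci] else irr,
                           c_motion = if (conds$context[ci] == "motion")
                             conds$coherence[ci] else irr,
                           dt = params$dt)
        pert$simulate(build_trial(spec, noise = FALSE), noise = FALSE)$r
      })
      act$rates[, ci, ] <- t(Reduce(`+`, reps) / length(reps))
    }
    act
  }
  stim_bins <- window_bins(base_act, "stim")
  conds <- base_act$conditions
  disp <- vapply(seq_len(nrow(conds)), function(ci) {
    tb <- project_trajectory(t(base_act$rates[, ci, stim_bins]),
                             subspace, dims)
    tp <- project_trajectory(t(pert_act$rates[, ci, stim_bins]),
                             subspace, dims)
    mean(sqrt(rowSums((tb - tp)^2)))
  }, numeric(1))
  ordering <- vapply(c("color", "motion"), function(ctx) {
    sel <- which(conds$context == ctx)
    endp <- t(vapply(sel, function(ci) {
      project_trajectory(pert_act$rates[, ci, max(stim_bins)],
                         subspace, dims)[1, ]
    }, numeric(dims)))
    base_endp <- t(vapply(sel, function(ci) {
      project_trajectory(base_act$rates[, ci, max(stim_bins)],
                         subspace, dims)[1, ]
    }, numeric(dims)))
    # direction of evidence ordering from the baseline endpoints
    co <- conds$coherence[sel]
    dir <- as.numeric(coef(lm(base_endp ~ co))[2, ])
    dir <- dir / sqrt(sum(dir^2))
    proj <- as.numeric(endp %*% dir)
    all(diff(proj[order(co)]) > 0)
  }, logical(1))
  list(displacement = data.frame(conds, displacement = disp),
       ordering_preserved = ordering,
       n_violations = sum(!ordering))
}
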