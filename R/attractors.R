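#' Dynamics speed q(x)
#'
#' `q(x) = 0.5 * ||x_dot||^2` with
#' `x_dot = (-x + W_rec softplus(x) + W_in u + b) / tau`, evaluated with
#' noise off under a constant input. Zero exactly at a fixed point.
#'
#' @param x state vector (length N).
#' @param u_const constant input vector (length 6).
#' @param params [rnn_params()].
#' @return scalar q >= 0.
#' @export
state_speed <- function(x, u_const, params) {
  xd <- (-x + as.numeric(params$W_rec %*% softplus(x) +
                           params$W_in %*% u_const) + params$b) / params$tau
  0.5 * sum(xd^2)
}

# gradient of q wrt x, via the analytic Jacobian of x_dot
state_speed_grad <- function(x, u_const, params) {
  xd <- (-x + as.numeric(params$W_rec %*% softplus(x) +
                           params$W_in %*% u_const) + params$b) / params$tau
  J <- rnn_jacobian(x, params)
  as.numeric(crossprod(J, xd))
}

#' Jacobian of the continuous-time dynamics
#'
#' `d x_dot / dx = (-I + W_rec diag(f'(x))) / tau` at state `x`. Its
#' eigenvalues' real parts determine local stability of the continuous
#' flow.
#'
#' @param x state vector.
#' @param params [rnn_params()].
#' @return N x N Jacobian matrix.
#' @export
rnn_jacobian <- function(x, params) {
  (-diag(params$N) +
     params$W_rec * rep(softplus_prime(as.numeric(x)),
                        each = params$N)) / params$tau
}

#' Constant search input for a trial condition
#'
#' The fixed-point search runs under the sensory-stimulus-epoch input:
#' cue units off, both modality channels at their clean stimulus
#' strengths.
#'
#' @param context `"color"` or `"motion"` (kept for bookkeeping; the input
#'   itself carries no cue).
#' @param coherence relevant signed coherence.
#' @param coherence_irrelevant irrelevant modality coherence (default 0,
#'   the mean of the coherence set).
#' @param gamma_bar mean stimulus strength.
#' @return length-6 input vector.
#' @export
condition_input <- function(context, coherence, coherence_irrelevant = 0,
                            gamma_bar = 1) {
  c_col <- if (context == "color") coherence else coherence_irrelevant
  c_mot <- if (context == "motion") coherence else coherence_irrelevant
  c(0, 0, stimulus_strengths(gamma_bar, c_col),
    stimulus_strengths(gamma_bar, c_mot))
}

# Gauss-Newton (Levenberg-Marquardt) descent on the residual x_dot(x) = 0
# with the analytic Jacobian. LM's trust region handles far
# initializations directly; an optional quasi-Newton descent on q can be
# prepended (maxit_bfgs > 0) but empirically stalls on slow points more
# often than LM alone.
polish_candidate <- function(x0, u_const, params, maxit_bfgs = 0,
                             maxit_lm = 200) {
  o <- if (maxit_bfgs > 0) {
    optim(x0, fn = state_speed, gr = state_speed_grad,
          u_const = u_const, params = params, method = "BFGS",
          control = list(maxit = maxit_bfgs, reltol = 1e-12))
  } else {
    list(par = x0)
  }
  resid <- function(x) {
    (-x + as.numeric(params$W_rec %*% softplus(x) +
                       params$W_in %*% u_const) + params$b) / params$tau
  }
  jac <- function(x) rnn_jacobian(x, params)
  # iteration-cap terminations are expected on slow points and are
  # reflected in the converged flag, so LM's warnings are muted
  lm <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = o$par, fn = resid, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit_lm, ftol = 1e-15,
                           ptol = 1e-15))),
    error = function(e) NULL)
  if (is.null(lm)) {
    return(list(x = o$par, q = state_speed(o$par, u_const, params),
                converged = FALSE))
  }
  list(x = lm$par, q = 0.5 * sum(resid(lm$par)^2),
       converged = lm$info %in% 1:4)
}

#' Find fixed points and slow points
#'
#' Minimizes `q(x)` from `n_restarts` random initial conditions under a
#' constant input, by Levenberg-Marquardt descent on the residual
#' `x_dot(x)` with the analytic Jacobian (optionally preceded by a
#' quasi-Newton descent on q itself).
#' Initial conditions are sampled either from a Gaussian ball around a
#' reference state (`init = "trajectory"`, the protocol for fixed points,
#' with the reference taken as the trajectory's state at stimulus onset)
#' or as i.i.d. standard normal states (`init = "gaussian"`, the
#' slow-point protocol). Candidates are deduplicated by pairwise distance
#' and classed by their final speed: fixed (`q < 1e-4`), slow
#' (`q < 1e-2`), otherwise rejected.
#'
#' @param params [rnn_params()].
#' @param u_const constant input (see [condition_input()]).
#' @param x_ref reference state for `init = "trajectory"`.
#' @param n_restarts number of optimization restarts.
#' @param init `"trajectory"` or `"gaussian"`.
#' @param init_sd Gaussian ball radius around `x_ref`.
#' @param dedup_dist candidates closer than this are merged (the one with
#'   smaller q is kept).
#' @param q_fixed,q_slow classification thresholds.
#' @param maxit_bfgs,maxit_lm iteration caps for the quasi-Newton descent
#'   and the Gauss-Newton polish.
#' @return data.frame with one row per retained candidate: `q`, `class`,
#'   `n_hits` (restarts merged into it), and the state in the `x` list
#'   column.
#' @export
find_fixed_points <- function(params, u_const, x_ref = NULL,
                              n_restarts = 300,
                              init = c("trajectory", "gaussian"),
                              init_sd = 0.5, dedup_dist = 0.1,
                              q_fixed = 1e-4, q_slow = 1e-2,
                              maxit_bfgs = 0, maxit_lm = 200) {
  init <- match.arg(init)
  if (init == "trajectory" && is.null(x_ref)) {
    stop("init = 'trajectory' needs a reference state x_ref")
  }
  cands <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    x0 <- if (init == "trajectory") {
      as.numeric(x_ref) + rnorm(params$N, 0, init_sd)
    } else {
      rnorm(params$N)
    }
    cands[[i]] <- polish_candidate(x0, u_const, params,
                                   maxit_bfgs = maxit_bfgs,
                                   maxit_lm = maxit_lm)
  }
  qs <- vapply(cands, `[[`, numeric(1), "q")
  xs <- do.call(rbind, lapply(cands, `[[`, "x"))
  ok <- vapply(cands, `[[`, logical(1), "converged")
  cls <- ifelse(!ok & qs >= q_slow, "rejected",
                ifelse(qs < q_fixed, "fixed",
                       ifelse(qs < q_slow, "slow", "rejected")))
  dd <- dedup_points(xs, qs, dedup_dist)
  data.frame(q = qs[dd$keep], class = cls[dd$keep], n_hits = dd$n_hits,
             x = I(lapply(dd$keep, function(i) xs[i, ])))
}

# greedy dedup: visit candidates by increasing q, absorb all others within
# dedup_dist. Idempotent: re-running on the survivors changes nothing.
dedup_points <- function(xs, qs, dedup_dist) {
  ord <- order(qs)
  keep <- integer(0)
  n_hits <- integer(0)
  taken <- rep(FALSE, nrow(xs))
  for (i in ord) {
    if (taken[i]) next
    d <- sqrt(rowSums((xs - rep(xs[i, ], each = nrow(xs)))^2))
    grp <- which(!taken & d < dedup_dist)
    taken[grp] <- TRUE
    keep <- c(keep, i)
    n_hits <- c(n_hits, length(grp))
  }
  list(keep = keep, n_hits = n_hits)
}

#' Empirical stability of a fixed point
#'
#' Probes stability the way it is defined for the trained network:
#' `n_probes` noise-free simulations are started from states perturbed by
#' radius `radius` around the candidate, run for `horizon` steps under the
#' constant input, and the point is stable iff every probe ends within
#' `eps` of it. The spectral abscissa of the continuous-time Jacobian is
#' returned as a diagnostic.
#'
#' @param x fixed-point state.
#' @param params [rnn_params()].
#' @param u_const constant input.
#' @param n_probes number of perturbed probes.
#' @param radius perturbation radius (state units).
#' @param eps return tolerance.
#' @param horizon probe length in steps.
#' @return list with `stable`, `max_final_dist`, `jac_abscissa`.
#' @export
classify_stability <- function(x, params, u_const, n_probes = 10,
                               radius = 0.2, eps = 0.05, horizon = 100) {
  x <- as.numeric(x)
  finals <- vapply(seq_len(n_probes), function(i) {
    d <- rnorm(params$N)
    xp <- x + radius * d / sqrt(sum(d^2))
    r <- softplus(xp)
    for (s in seq_len(horizon)) {
      st <- rnn_step(xp, r, u_const, params, noise = FALSE)
      xp <- as.numeric(st$x)
      r <- st$r
    }
    d <- sqrt(sum((xp - x)^2))
    if (!is.finite(d)) d <- Inf      # diverged probe
    d
  }, numeric(1))
  jac <- max(Re(eigen(rnn_jacobian(x, params),
                      only.values = TRUE)$values))
  list(stable = all(finals <= eps), max_final_dist = max(finals),
       jac_abscissa = jac)
}

#' Attractor search over all trial conditions
#'
#' Runs the fixed-point protocol for each of the 16 canonical conditions:
#' simulate the condition noise-free, take the state at stimulus onset as
#' the init reference, search under the condition's constant sensory
#' input, keep stable fixed points, and select as the condition's
#' attractor the stable fixed point nearest the trajectory's
#' end-of-stimulus state. Conditions whose search yields no stable fixed
#' point report `NA`.
#'
#' @param params [rnn_params()].
#' @param n_restarts restarts per condition.
#' @param q_fixed fixed-point threshold.
#' @param stability_args list of overrides for [classify_stability()].
#' @param ... passed to [find_fixed_points()].
#' @return list with `table` (one row per condition: context, coherence,
#'   q, stable, distance to trajectory endpoint), `points` (list of
#'   attractor states or NULL), `endpoints` (16 x N matrix of
#'   end-of-stimulus states), `n_attractors`.
#' @export
condition_attractors <- function(params, n_restarts = 300, q_fixed = 1e-4,
                                 stability_args = list(), ...) {
  conds <- condition_grid()
  act_free <- condition_activity(params, noise = FALSE)
  durations <- default_durations()
  ep <- epoch_labels(durations, params$dt)
  pre_stim <- max(which(ep == "delay"))
  end_stim <- max(which(ep == "stim"))
  points <- vector("list", nrow(conds))
  endpoints <- matrix(0, nrow(conds), params$N)
  rows <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    spec <- trial_spec(conds$context[ci],
                       c_color = if (conds$context[ci] == "color")
                         conds$coherence[ci] else 0,
                       c_motion = if (conds$context[ci] == "motion")
                         conds$coherence[ci] else 0,
                       dt = params$dt)
    trial <- build_trial(spec, noise = FALSE)
    sim <- simulate_trial(params, trial, noise = FALSE)
    x_ref <- sim$x[pre_stim, ]
    x_end <- sim$x[end_stim, ]
    endpoints[ci, ] <- x_end
    u_const <- condition_input(conds$context[ci], conds$coherence[ci])
    fps <- find_fixed_points(params, u_const, x_ref = x_ref,
                             n_restarts = n_restarts, q_fixed = q_fixed,
                             ...)
    fixed <- fps[fps$class == "fixed", , drop = FALSE]
    best <- NULL
    if (nrow(fixed) > 0) {
      stab <- lapply(fixed$x, function(xf) {
        do.call(classify_stability,
                c(list(x = xf, params = params, u_const = u_const),
                  stability_args))
      })
      ok <- which(vapply(stab, `[[`, logical(1), "stable"))
      if (length(ok) > 0) {
        dists <- vapply(ok, function(i) {
          sqrt(sum((fixed$x[[i]] - x_end)^2))
        }, numeric(1))
        best <- ok[which.min(dists)]
      }
    }
    if (is.null(best)) {
      rows[[ci]] <- data.frame(context = conds$context[ci],
                               coherence = conds$coherence[ci],
                               q = NA_real_, stable = FALSE,
                               dist_to_end = NA_real_)
    } else {
      points[[ci]] <- fixed$x[[best]]
      rows[[ci]] <- data.frame(context = conds$context[ci],
                               coherence = conds$coherence[ci],
                               q = fixed$q[best], stable = TRUE,
                               dist_to_end = sqrt(sum((fixed$x[[best]] -
                                                         x_end)^2)))
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, points = points, endpoints = endpoints,
       n_attractors = sum(tab$stable), conditions = conds)
}

#' Line-attractor alignment summary
#'
#' For each context, fits the principal line through the (subspace-
#' projected) fixed points and reports how one-dimensional their
#' arrangement is (collinearity = fraction of variance on the line), the
#' mean distance of the trajectory endpoints (manifold M) to that line,
#' and whether each condition's endpoint lies nearer its own context's
#' attractor set than the other context's.
#'
#' @param points n x N matrix of fixed-point states (rows), or the list
#'   from [condition_attractors()].
#' @param contexts per-point context labels.
#' @param subspace a `subspace` used for the projection.
#' @param endpoints matrix of per-condition trajectory endpoints.
#' @param endpoint_contexts per-endpoint context labels.
#' @param dims projection dimension.
#' @return data.frame, one row per context: `n_points`, `collinearity`,
#'   `mean_endpoint_residual`, `frac_nearest_own`.
#' @export
line_attractor_summary <- function(points, contexts, subspace, endpoints,
                                   endpoint_contexts = contexts, dims = 3) {
  P <- project_trajectory(as.matrix(points), subspace, dims)
  E <- project_trajectory(as.matrix(endpoints), subspace, dims)
  out <- lapply(unique(contexts), function(ctx) {
    Pi <- P[contexts == ctx, , drop = FALSE]
    Ei <- E[endpoint_contexts == ctx, , drop = FALSE]
    if (nrow(Pi) < 2) {
      return(data.frame(context = ctx, n_points = nrow(Pi),
                        collinearity = NA_real_,
                        mean_endpoint_residual = NA_real_,
                        frac_nearest_own = NA_real_))
    }
    ctr <- colMeans(Pi)
    sv <- svd(sweep(Pi, 2, ctr))
    collin <- sv$d[1]^2 / sum(sv$d^2)
    dir <- sv$v[, 1]
    resid <- vapply(seq_len(nrow(Ei)), function(i) {
      d <- Ei[i, ] - ctr
      sqrt(sum((d - sum(d * dir) * dir)^2))
    }, numeric(1))
    # nearest-attractor check in the full projected space
    own <- Pi
    other <- P[contexts != ctx, , drop = FALSE]
    near_own <- vapply(seq_len(nrow(Ei)), function(i) {
      d_own <- min(sqrt(rowSums((own - rep(Ei[i, ],
                                           each = nrow(own)))^2)))
      d_oth <- if (nrow(other) == 0) Inf else
        min(sqrt(rowSums((other - rep(Ei[i, ], each = nrow(other)))^2)))
      d_own < d_oth
    }, logical(1))
    data.frame(context = ctx, n_points = nrow(Pi), collinearity = collin,
               mean_endpoint_residual = mean(resid),
               frac_nearest_own = mean(near_own))
  })
  do.call(rbind, out)
}
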