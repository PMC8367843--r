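#' Numerically stable softplus
#'
#' `f(x) = log(1 + exp(x))`, computed as `log1p(exp(x))` with an asymptotic
#' branch `f(x) ~ x` for large arguments so the result never overflows.
#' Maps any current to a strictly positive firing rate.
#'
#' @param x numeric vector, matrix or array of currents.
#' @return firing rates, same shape as `x`.
#' @export
softplus <- function(x) {
  out <- x
  low <- x <= 30
  out[low] <- log1p(exp(x[low]))
  out
}

# derivative of softplus = logistic sigmoid
softplus_prime <- function(x) 1 / (1 + exp(-x))

#' Rate-network parameters
#'
#' Container for all weights, biases, time constants and noise scales of
#' the rate model
#' \deqn{\tau \dot x = -x + W_{rec} f(x) + W_{in} u + b + \sqrt{2\tau\sigma_{rec}^2}\,\xi,
#'       \quad z = W_{out} f(x) + b_{out}}
#' with softplus transfer `f`. The Euler discretization with
#' `alpha = dt / tau` is
#' `x_t = (1 - alpha) x_{t-1} + alpha (W_rec r_{t-1} + W_in u_t + b + sqrt(2/alpha) sigma_rec xi)`.
#'
#' @param W_in N x 6 input weights.
#' @param W_rec N x N recurrent weights.
#' @param W_out 4 x N output weights.
#' @param b recurrent bias (length N).
#' @param b_out output bias (length 4).
#' @param tau synaptic time constant, ms.
#' @param dt simulation step, ms.
#' @param sigma_rec recurrent (intrinsic) noise scale.
#' @param sigma_in input noise scale.
#' @return object of class `rnn_params` (with `N` and `alpha` filled in).
#' @export
rnn_params <- function(W_in, W_rec, W_out, b, b_out,
                       tau = 20, dt = 20, sigma_rec = 0.05, sigma_in = 0.01) {
  N <- nrow(W_rec)
  stopifnot(ncol(W_rec) == N, nrow(W_in) == N, ncol(W_in) == 6,
            nrow(W_out) == 4, ncol(W_out) == N,
            length(b) == N, length(b_out) == 4,
            tau > 0, dt > 0, sigma_rec >= 0, sigma_in >= 0)
  structure(
    list(W_in = W_in, W_rec = W_rec, W_out = W_out,
         b = as.numeric(b), b_out = as.numeric(b_out),
         tau = tau, dt = dt, alpha = dt / tau,
         sigma_rec = sigma_rec, sigma_in = sigma_in, N = N),
    class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf(
    "rnn_params: N = %d, tau = %g ms, dt = %g ms (alpha = %g), sigma_rec = %g, sigma_in = %g\n",
    x$N, x$tau, x$dt, x$alpha, x$sigma_rec, x$sigma_in))
  invisible(x)
}

#' One Euler step of the discretized dynamics
#'
#' `x_t = (1 - alpha) x_{t-1} + alpha (W_rec r_{t-1} + W_in u_t + b + noise)`
#' where the noise term is `sqrt(2 / alpha) * sigma_rec * xi` with standard
#' normal `xi`, and `r_t = softplus(x_t)`. Accepts a state matrix with one
#' column per batch trial.
#'
#' @param x_prev N (x B) current state.
#' @param r_prev N (x B) previous rates.
#' @param u_t length-6 input (or 6 x B matrix for a batch).
#' @param params [rnn_params()].
#' @param noise logical; `FALSE` gives the deterministic update.
#' @return list with `x` and `r`.
#' @export
rnn_step <- function(x_prev, r_prev, u_t, params, noise = TRUE) {
  x_prev <- as.matrix(x_prev)
  r_prev <- as.matrix(r_prev)
  u_t <- if (is.matrix(u_t)) u_t else matrix(u_t, ncol = 1)
  if (nrow(x_prev) != params$N || nrow(u_t) != 6 ||
      !all(dim(x_prev) == dim(r_prev)) || ncol(u_t) != ncol(x_prev)) {
    stop("shape mismatch in rnn_step")
  }
  a <- params$alpha
  drive <- params$W_rec %*% r_prev + params$W_in %*% u_t + params$b
  if (noise && params$sigma_rec > 0) {
    drive <- drive + sqrt(2 / a) * params$sigma_rec *
      matrix(rnorm(length(x_prev)), nrow(x_prev), ncol(x_prev))
  }
  x <- (1 - a) * x_prev + a * drive
  list(x = x, r = softplus(x))
}

#' Simulate one trial
#'
#' Runs the discretized dynamics over a trial's input, from initial state
#' `x0` (zero by default), and reads out `z = W_out r + b_out` at every
#' step.
#'
#' @param params [rnn_params()].
#' @param trial a [build_trial()] result (its `u` drives the network).
#' @param noise logical; recurrent noise on/off.
#' @param x0 initial state (length N), default zeros.
#' @return list with matrices `x`, `r` (T x N) and `z` (T x 4), plus the
#'   trial's `epoch` labels.
#' @export
simulate_trial <- function(params, trial, noise = TRUE, x0 = NULL) {
  u <- t(trial$u)                      # 6 x T
  nt <- ncol(u)
  x <- if (is.null(x0)) rep(0, params$N) else as.numeric(x0)
  r <- softplus(x)
  X <- matrix(0, nt, params$N)
  R <- matrix(0, nt, params$N)
  Z <- matrix(0, nt, 4)
  for (t in seq_len(nt)) {
    st <- rnn_step(x, r, u[, t], params, noise = noise)
    x <- st$x
    r <- st$r
    X[t, ] <- x
    R[t, ] <- r
    Z[t, ] <- params$W_out %*% r + params$b_out
  }
  list(x = X, r = R, z = Z, epoch = trial$epoch)
}

# Batched forward pass used by training and condition averaging.
# U: 6 x B x T input array. Returns rates array N x B x T (and currents).
forward_batch <- function(params, U, noise = TRUE, keep_states = TRUE) {
  N <- params$N
  B <- dim(U)[2]
  nt <- dim(U)[3]
  a <- params$alpha
  x <- matrix(0, N, B)
  r <- softplus(x)
  X <- if (keep_states) array(0, c(N, B, nt)) else NULL
  R <- array(0, c(N, B, nt))
  Z <- array(0, c(4, B, nt))
  for (t in seq_len(nt)) {
    drive <- params$W_rec %*% r + params$W_in %*% U[, , t] + params$b
    if (noise && params$sigma_rec > 0) {
      drive <- drive + sqrt(2 / a) * params$sigma_rec * matrix(rnorm(N * B), N, B)
    }
    x <- (1 - a) * x + a * drive
    r <- softplus(x)
    if (keep_states) X[, , t] <- x
    R[, , t] <- r
    Z[, , t] <- params$W_out %*% r + params$b_out
  }
  list(X = X, R = R, Z = Z)
}

# Clean (noise-free) input array for a set of trial specs; 6 x B x T.
input_array <- function(specs, durations = default_durations(), dt = 20,
                        sigma_in = 0, cue_amplitude = 1) {
  ep <- epoch_labels(durations, dt)
  nt <- length(ep)
  B <- nrow(specs)
  U <- array(0, c(6, B, nt))
  cue <- ep == "cue"
  stim <- ep == "stim"
  U[1, specs$context == "color", cue] <- cue_amplitude
  U[2, specs$context == "motion", cue] <- cue_amplitude
  U[3, , stim] <- specs$gamma_bar_color + specs$c_color
  U[4, , stim] <- specs$gamma_bar_color - specs$c_color
  U[5, , stim] <- specs$gamma_bar_motion + specs$c_motion
  U[6, , stim] <- specs$gamma_bar_motion - specs$c_motion
  if (sigma_in > 0) {
    U <- U + sqrt(2 * sigma_in^2) * array(rnorm(length(U)), dim(U))
  }
  U
}

#' Condition-averaged population activity
#'
#' Simulates the network over the 16 canonical conditions (2 contexts x 8
#' relevant coherences) and returns trial-averaged firing rates as an
#' activity tensor (units x conditions x time). The irrelevant modality's
#' coherence is marginalized: either by running the full 8 x 8 coherence
#' grid noise-free and averaging over the irrelevant values
#' (`noise = FALSE`, deterministic), or by averaging `n_reps` noisy trials
#' with the irrelevant coherence resampled per trial.
#'
#' @param params [rnn_params()].
#' @param noise logical; noisy trial-averaged (`TRUE`) or noise-free grid
#'   (`FALSE`).
#' @param n_reps noisy repetitions per condition (ignored when
#'   `noise = FALSE`).
#' @param gamma_bar mean stimulus strength used for all conditions.
#' @param durations,dt trial timing.
#' @return object of class `activity_tensor`: list with `rates`
#'   (N x 16 x T array), `epoch` labels, `conditions` data.frame, `dt`.
#' @export
condition_activity <- function(params, noise = FALSE, n_reps = 20,
                               gamma_bar = 1,
                               durations = default_durations(),
                               dt = params$dt) {
  conds <- condition_grid()
  if (noise) {
    grid <- conds[rep(seq_len(nrow(conds)), each = n_reps), ]
    irr <- sample_coherence(nrow(grid))
    key <- rep(seq_len(nrow(conds)), each = n_reps)
  } else {
    grid <- conds[rep(seq_len(nrow(conds)), each = length(coherence_set)), ]
    irr <- rep(coherence_set, times = nrow(conds))
    key <- rep(seq_len(nrow(conds)), each = length(coherence_set))
  }
  specs <- data.frame(
    context = grid$context,
    c_color = ifelse(grid$context == "color", grid$coherence, irr),
    c_motion = ifelse(grid$context == "motion", grid$coherence, irr),
    gamma_bar_color = gamma_bar, gamma_bar_motion = gamma_bar)
  U <- input_array(specs, durations, dt,
                   sigma_in = if (noise) params$sigma_in else 0)
  fwd <- forward_batch(params, U, noise = noise, keep_states = FALSE)
  ep <- epoch_labels(durations, dt)
  nt <- length(ep)
  rates <- array(0, c(params$N, nrow(conds), nt))
  for (i in seq_len(nrow(conds))) {
    rates[, i, ] <- apply(fwd$R[, key == i, , drop = FALSE], c(1, 3), mean)
  }
  structure(list(rates = rates, epoch = ep, conditions = conds, dt = dt),
            class = "activity_tensor")
}

#' @export
print.activity_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("activity_tensor: %d units x %d conditions x %d bins (dt = %g ms)\n",
              d[1], d[2], d[3], x$dt))
  invisible(x)
}
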