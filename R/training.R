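#' Initialize network parameters
#'
#' Recurrent off-diagonal weights are independent Gaussian with mean 0; the
#' diagonal (self-connections) starts at exactly 1. Input weights are
#' uniform on \[-0.5, 0.5\]; output weights Gaussian; biases zero. The
#' Gaussian scales default to `0.3 / N` (recurrent) and `0.4 / N` (output):
#' together with the unit diagonal this keeps the spectral radius of
#' `W_rec` near `1 + 0.3 / sqrt(N)`, which is the edge-of-stability regime
#' the discretized dynamics need — a `0.3 / sqrt(N)` off-diagonal scale
#' would put the radius near 1.3 and the forward pass diverges over a
#' trial. Set `scale_by_sqrt_n = TRUE` to use the `1 / sqrt(N)` convention
#' anyway.
#'
#' @param N number of recurrent units (>= 2).
#' @param rec_scale,out_scale numerators of the weight scales.
#' @param scale_by_sqrt_n divide scales by `sqrt(N)` instead of `N`.
#' @param ... further arguments passed to [rnn_params()] (tau, dt,
#'   sigma_rec, sigma_in).
#' @return an [rnn_params()] object.
#' @export
init_params <- function(N = 256, rec_scale = 0.3, out_scale = 0.4,
                        scale_by_sqrt_n = FALSE, ...) {
  if (N < 2) stop("N must be at least 2")
  denom <- if (scale_by_sqrt_n) sqrt(N) else N
  W_rec <- matrix(rnorm(N * N, 0, rec_scale / denom), N, N)
  diag(W_rec) <- 1
  W_in <- matrix(runif(N * 6, -0.5, 0.5), N, 6)
  W_out <- matrix(rnorm(4 * N, 0, out_scale / denom), 4, N)
  rnn_params(W_in, W_rec, W_out, b = rep(0, N), b_out = rep(0, 4), ...)
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam exponential decay rates for the first and second
#'   moment estimates.
#' @param batch_size trials per gradient step.
#' @param max_steps upper bound on gradient steps.
#' @param loss_threshold,perf_threshold convergence criteria: training
#'   stops once the evaluated loss is at or below `loss_threshold` and the
#'   fraction correct is at or above `perf_threshold`.
#' @param eval_every evaluate and record curves every this many steps.
#' @param eval_trials trials used per performance evaluation.
#' @param grad_clip if finite, clip the global gradient norm to this value.
#' @param seed RNG seed for the whole run (initialization, batches, noise).
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 64, max_steps = 20000,
                         loss_threshold = 0.01, perf_threshold = 0.95,
                         eval_every = 100, eval_trials = 256,
                         grad_clip = Inf, seed = 1) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = batch_size, max_steps = max_steps,
                 loss_threshold = loss_threshold,
                 perf_threshold = perf_threshold,
                 eval_every = eval_every, eval_trials = eval_trials,
                 grad_clip = grad_clip, seed = seed),
            class = "train_config")
}

#' Mean squared error loss
#'
#' Mean of `(z - z_hat)^2` over output units and (optionally masked)
#' timesteps, i.e. the per-unit average squared readout error that training
#' minimizes.
#'
#' @param z network output (T x N_out matrix, or array with time last).
#' @param z_hat target of the same shape.
#' @param mask logical vector over timesteps selecting scored steps;
#'   default all.
#' @return scalar loss.
#' @export
mse_loss <- function(z, z_hat, mask = NULL) {
  if (!all(dim(z) == dim(z_hat))) stop("z and z_hat shapes differ")
  if (is.null(mask)) return(mean((z - z_hat)^2))
  if (!any(mask)) stop("empty mask")
  if (is.matrix(z)) {
    mean((z[mask, , drop = FALSE] - z_hat[mask, , drop = FALSE])^2)
  } else {
    nd <- length(dim(z))
    idx <- rep(list(quote(expr = )), nd)
    idx[[nd]] <- which(mask)
    mean((do.call(`[`, c(list(z), idx)) - do.call(`[`, c(list(z_hat), idx)))^2)
  }
}

# Random training batch: clean + noisy inputs and targets for B trials.
# Returns U (6 x B x T), Zhat (4 x B x T), and per-trial metadata.
training_batch <- function(B, params, durations = default_durations(),
                           baseline = 0.2, active = 1, balanced = FALSE) {
  if (balanced) {
    conds <- condition_grid()
    idx <- rep_len(seq_len(nrow(conds)), B)
    context <- conds$context[idx]
    rel <- conds$coherence[idx]
  } else {
    context <- sample(c("color", "motion"), B, replace = TRUE)
    rel <- sample_coherence(B)
  }
  irr <- sample_coherence(B)
  specs <- data.frame(
    context = context,
    c_color = ifelse(context == "color", rel, irr),
    c_motion = ifelse(context == "motion", rel, irr),
    gamma_bar_color = runif(B, 0.8, 1.2),
    gamma_bar_motion = runif(B, 0.8, 1.2))
  U <- input_array(specs, durations, params$dt, sigma_in = params$sigma_in)
  ep <- epoch_labels(durations, params$dt)
  nt <- length(ep)
  Zhat <- array(baseline, c(4, B, nt))
  resp <- which(ep == "resp")
  ch1 <- rel > 0
  Zhat[1:2, ch1, resp] <- active
  Zhat[3:4, !ch1, resp] <- active
  list(U = U, Zhat = Zhat, specs = specs, epoch = ep, relevant = rel)
}

# Forward + backward pass through time. Returns loss and parameter
# gradients. The loss is the mean squared output error over all scored
# timesteps (mask TRUE), output units and batch trials; pre-response steps
# act as a fixation penalty because their targets sit at baseline.
bptt_grad <- function(params, U, Zhat, mask = NULL, noise = TRUE) {
  N <- params$N
  B <- dim(U)[2]
  nt <- dim(U)[3]
  a <- params$alpha
  if (is.null(mask)) mask <- rep(TRUE, nt)
  if (!any(mask)) stop("empty mask")
  fwd <- forward_batch(params, U, noise = noise, keep_states = TRUE)
  M <- 4 * B * sum(mask)
  loss <- 0
  dZ <- array(0, c(4, B, nt))
  for (t in which(mask)) {
    e <- fwd$Z[, , t] - Zhat[, , t]
    loss <- loss + sum(e^2)
    dZ[, , t] <- 2 * e / M
  }
  loss <- loss / M
  gW_out <- matrix(0, 4, N)
  gb_out <- rep(0, 4)
  gW_rec <- matrix(0, N, N)
  gW_in <- matrix(0, N, 6)
  gb <- rep(0, N)
  dx_next <- matrix(0, N, B)
  r0 <- softplus(matrix(0, N, B))
  for (t in rev(seq_len(nt))) {
    r_t <- fwd$R[, , t]
    dr <- crossprod(params$W_out, dZ[, , t]) +
      a * crossprod(params$W_rec, dx_next)
    dx <- dr * softplus_prime(fwd$X[, , t]) + (1 - a) * dx_next
    gW_out <- gW_out + tcrossprod(dZ[, , t], r_t)
    gb_out <- gb_out + rowSums(dZ[, , t])
    r_prev <- if (t > 1) fwd$R[, , t - 1] else r0
    gW_rec <- gW_rec + a * tcrossprod(dx, r_prev)
    gW_in <- gW_in + a * tcrossprod(dx, U[, , t])
    gb <- gb + a * rowSums(dx)
    dx_next <- dx
  }
  list(loss = loss,
       grads = list(W_rec = gW_rec, W_in = gW_in, W_out = gW_out,
                    b = gb, b_out = gb_out))
}

#' Evaluate task performance
#'
#' Fraction of correct choices over noisy trials balanced across the 16
#' canonical conditions. Ambiguous (tied) outputs count as incorrect.
#'
#' @param params [rnn_params()].
#' @param n_trials number of evaluation trials.
#' @param durations epoch durations.
#' @return fraction correct in \[0, 1\].
#' @export
evaluate_performance <- function(params, n_trials = 256,
                                 durations = default_durations()) {
  batch <- training_batch(n_trials, params, durations, balanced = TRUE)
  fwd <- forward_batch(params, batch$U, noise = TRUE, keep_states = FALSE)
  resp <- which(batch$epoch == "resp")
  m1 <- apply(fwd$Z[1:2, , resp, drop = FALSE], 2, mean)
  m2 <- apply(fwd$Z[3:4, , resp, drop = FALSE], 2, mean)
  chosen1 <- m1 > m2
  tie <- m1 == m2
  mean(!tie & (chosen1 == (batch$relevant > 0)))
}

#' Train a network with BPTT and Adam
#'
#' Optimizes all weights and biases by backpropagation through the full
#' trial, using Adam. Training stops when the smoothed loss is at or below
#' `config$loss_threshold` and the evaluated performance is at or above
#' `config$perf_threshold`, or after `config$max_steps` steps. The run is
#' fully seeded and reproducible.
#'
#' @param params starting parameters, e.g. [init_params()]; if `NULL` a
#'   fresh initialization of size `N` is drawn under the config seed.
#' @param config a [train_config()].
#' @param N network size used when `params` is `NULL`.
#' @param durations epoch durations for the task.
#' @param verbose print progress lines at evaluation points.
#' @param time_limit wall-clock cap in minutes, checked at evaluation
#'   points; `Inf` disables it.
#' @return list with `params` (trained), `curves` (data.frame of step,
#'   loss, performance), and `converged` flag.
#' @export
train_rnn <- function(params = NULL, config = train_config(), N = 256,
                      durations = default_durations(), verbose = FALSE,
                      time_limit = Inf) {
  t_start <- Sys.time()
  set.seed(config$seed)
  if (is.null(params)) params <- init_params(N)
  wkeys <- c("W_rec", "W_in", "W_out", "b", "b_out")
  m <- lapply(params[wkeys], function(w) w * 0)
  v <- m
  curves <- list()
  converged <- FALSE
  for (step in seq_len(config$max_steps)) {
    batch <- training_batch(config$batch_size, params, durations)
    fb <- bptt_grad(params, batch$U, batch$Zhat)
    if (!is.finite(fb$loss)) {
      stop(sprintf("training diverged at step %d (non-finite loss)", step))
    }
    g <- fb$grads
    if (is.finite(config$grad_clip)) {
      gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
      if (gn > config$grad_clip) {
        g <- lapply(g, function(x) x * config$grad_clip / gn)
      }
    }
    for (k in wkeys) {
      m[[k]] <- config$beta1 * m[[k]] + (1 - config$beta1) * g[[k]]
      v[[k]] <- config$beta2 * v[[k]] + (1 - config$beta2) * g[[k]]^2
      mhat <- m[[k]] / (1 - config$beta1^step)
      vhat <- v[[k]] / (1 - config$beta2^step)
      params[[k]] <- params[[k]] - config$lr * mhat / (sqrt(vhat) + 1e-8)
    }
    if (step %% config$eval_every == 0 || step == config$max_steps) {
      perf <- evaluate_performance(params, config$eval_trials, durations)
      curves[[length(curves) + 1]] <-
        data.frame(step = step, loss = fb$loss, performance = perf)
      if (verbose) {
        message(sprintf("step %d: loss %.4f, performance %.3f",
                        step, fb$loss, perf))
      }
      if (fb$loss <= config$loss_threshold &&
          perf >= config$perf_threshold) {
        converged <- TRUE
        break
      }
      if (as.numeric(difftime(Sys.time(), t_start, units = "mins")) >
          time_limit) {
        break
      }
    }
  }
  list(params = params, curves = do.call(rbind, curves),
       converged = converged)
}
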