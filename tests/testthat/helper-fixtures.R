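# Shared test fixtures. Heavy objects (trained networks) are built once
# per test run and memoized here.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, fixture_cache)) {
    assign(key, builder(), fixture_cache)
  }
  get(key, fixture_cache)
}

# small trained network + cached condition-averaged activity
fixture_net <- function() {
  memo("fixture", function() {
    make_fixture(seed = 42, N = 32, perf_target = 0.85, max_steps = 2500)
  })
}

# ensemble of trained networks for the statistical acceptance checks
trained_ensemble <- function() {
  memo("ensemble", function() {
    lapply(c(101, 202, 303), function(s) {
      cfg <- train_config(max_steps = 2500, loss_threshold = 0.003,
                          perf_threshold = 0.95, eval_every = 250,
                          eval_trials = 128, seed = s)
      fit <- train_rnn(NULL, cfg, N = 64)
      act <- condition_activity(fit$params, noise = FALSE)
      list(params = fit$params, activity = act,
           converged = fit$converged)
    })
  })
}

# deterministic tiny parameter set for shape/identity checks
toy_params <- function(N = 4, seed = 7, sigma_rec = 0.05, sigma_in = 0.01,
                       scale = 0.2) {
  set.seed(seed)
  rnn_params(W_in = matrix(runif(N * 6, -0.5, 0.5), N, 6),
             W_rec = matrix(rnorm(N * N, 0, scale / N), N, N),
             W_out = matrix(rnorm(4 * N, 0, 0.1), 4, N),
             b = rep(0, N), b_out = rep(0, 4),
             sigma_rec = sigma_rec, sigma_in = sigma_in)
}

# synthetic activity tensor with hand-placed unit responses.
# `responses` is a function(unit, condition row, epoch label) -> rate.
synthetic_activity <- function(n_units, responses,
                               durations = default_durations(), dt = 20) {
  ep <- epoch_labels(durations, dt)
  conds <- condition_grid()
  rates <- array(0, c(n_units, nrow(conds), length(ep)))
  for (u in seq_len(n_units)) {
    for (ci in seq_len(nrow(conds))) {
      rates[u, ci, ] <- vapply(ep, function(e) {
        responses(u, conds[ci, ], e)
      }, numeric(1))
    }
  }
  structure(list(rates = rates, epoch = ep, conditions = conds, dt = dt),
            class = "activity_tensor")
}

# logistic sigmoid, written out independently of the package internals
softplus_prime_oracle <- function(x) exp(x) / (1 + exp(x))

# shifted-Gaussian sequence activity: unit i peaks at bin peak[i]
sequence_rates <- function(n_units, nt, peaks, width = 2, amp = 10) {
  t(vapply(seq_len(n_units), function(i) {
    amp * exp(-(seq_len(nt) - peaks[i])^2 / (2 * width^2))
  }, numeric(nt)))
}
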