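#' Discrete coherence set used by the task
#'
#' Signed coherence values for either sensory modality. A trial's coherence
#' for each modality is drawn uniformly from this set.
#'
#' @export
coherence_set <- c(-0.08, -0.04, -0.02, -0.01, 0.01, 0.02, 0.04, 0.08)

#' Default epoch durations (ms)
#'
#' Fixation, context-cue, delay, sensory-stimulus and response epochs.
#' Cue (400 ms), delay (800 ms) and stimulus (800 ms) are fixed task
#' parameters; fixation and response defaults are 200 ms each and may be
#' overridden.
#'
#' @export
default_durations <- function() {
  c(fix = 200, cue = 400, delay = 800, stim = 800, resp = 200)
}

#' Sample signed coherences
#'
#' Draws uniformly from [coherence_set].
#'
#' @param n number of draws.
#' @return numeric vector of coherences.
#' @export
sample_coherence <- function(n = 1) {
  sample(coherence_set, n, replace = TRUE)
}

#' Stimulus strengths for one modality
#'
#' The two evidence streams of a modality have strengths
#' `gamma1 = gamma_bar + c` and `gamma2 = gamma_bar - c`, so their mean is
#' the overall stimulus strength and their signed difference is twice the
#' coherence.
#'
#' @param gamma_bar mean stimulus strength (dimensionless, nominally in
#'   \[0.8, 1.2\]).
#' @param c signed coherence.
#' @return numeric length-2 vector `c(gamma1, gamma2)`.
#' @export
stimulus_strengths <- function(gamma_bar, c) {
  c(gamma_bar + c, gamma_bar - c)
}

#' Per-bin epoch labels
#'
#' @param durations named epoch durations in ms (see [default_durations()]).
#' @param dt time step in ms; every duration must be divisible by `dt`.
#' @return character vector, one epoch label per time bin.
#' @export
epoch_labels <- function(durations = default_durations(), dt = 20) {
  if (any(durations < 0)) stop("epoch durations must be non-negative")
  if (any(durations %% dt != 0)) {
    stop("all epoch durations must be divisible by dt")
  }
  rep(names(durations), durations / dt)
}

#' Trial specification
#'
#' Bundles one trial's condition: the relevant context, the signed
#' coherences of the two modalities, the mean stimulus strengths, and the
#' epoch timing.
#'
#' @param context `"color"` or `"motion"`.
#' @param c_color,c_motion signed coherences of the color and motion
#'   modalities.
#' @param gamma_bar_color,gamma_bar_motion mean stimulus strengths; default 1.
#' @param durations named epoch durations in ms.
#' @param dt time step in ms.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(context = c("color", "motion"),
                       c_color = sample_coherence(),
                       c_motion = sample_coherence(),
                       gamma_bar_color = 1, gamma_bar_motion = 1,
                       durations = default_durations(), dt = 20) {
  context <- match.arg(context)
  if (any(durations %% dt != 0)) {
    stop("all epoch durations must be divisible by dt")
  }
  structure(
    list(context = context, c_color = c_color, c_motion = c_motion,
         gamma_bar_color = gamma_bar_color,
         gamma_bar_motion = gamma_bar_motion,
         durations = durations, dt = dt),
    class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("trial_spec: %s context, c_color = %+.2f, c_motion = %+.2f\n",
              x$context, x$c_color, x$c_motion))
  cat(sprintf("  gamma_bar = (%.2f, %.2f), dt = %g ms, epochs: %s\n",
              x$gamma_bar_color, x$gamma_bar_motion, x$dt,
              paste(sprintf("%s %g", names(x$durations), x$durations),
                    collapse = ", ")))
  invisible(x)
}

#' Relevant signed coherence of a trial
#'
#' @param spec a [trial_spec()].
#' @return the coherence of the context-relevant modality.
#' @export
relevant_coherence <- function(spec) {
  if (spec$context == "color") spec$c_color else spec$c_motion
}

#' Build one trial's input and target time series
#'
#' Input channels (columns of `u`): two one-hot context-cue units active
#' during the cue epoch (color = unit 1, motion = unit 2), two color
#' evidence units and two motion evidence units active during the sensory
#' stimulus epoch. Both modalities are always presented; only the context
#' determines which one is relevant. Independent Gaussian noise of standard
#' deviation `sqrt(2) * sigma_in` is added to every channel at every step.
#'
#' The target output holds all four output units at `baseline` except during
#' the response epoch, when the two units of the channel matching the sign
#' of the relevant evidence step up to `active`.
#'
#' @param spec a [trial_spec()].
#' @param sigma_in input noise scale.
#' @param noise logical; set `FALSE` for the noise-free clean signal.
#' @param cue_amplitude amplitude of the one-hot context cue.
#' @param baseline,active target output levels.
#' @return object of class `trial_input`: list with `u` (T x 6), `target`
#'   (T x 4), `epoch` (length-T labels), and the generating `spec`.
#' @export
build_trial <- function(spec, sigma_in = 0.01, noise = TRUE,
                        cue_amplitude = 1, baseline = 0.2, active = 1) {
  ep <- epoch_labels(spec$durations, spec$dt)
  nt <- length(ep)
  u <- matrix(0, nt, 6,
              dimnames = list(NULL, c("cue_color", "cue_motion",
                                      "color_1", "color_2",
                                      "motion_1", "motion_2")))
  cue <- ep == "cue"
  stim <- ep == "stim"
  if (spec$context == "color") u[cue, 1] <- cue_amplitude
  else u[cue, 2] <- cue_amplitude
  u[stim, 3:4] <- rep(stimulus_strengths(spec$gamma_bar_color, spec$c_color),
                      each = sum(stim))
  u[stim, 5:6] <- rep(stimulus_strengths(spec$gamma_bar_motion, spec$c_motion),
                      each = sum(stim))
  if (noise) u <- u + sqrt(2 * sigma_in^2) * matrix(rnorm(nt * 6), nt, 6)
  target <- matrix(baseline, nt, 4)
  resp <- ep == "resp"
  if (relevant_coherence(spec) > 0) target[resp, 1:2] <- active
  else target[resp, 3:4] <- active
  structure(list(u = u, target = target, epoch = ep, spec = spec),
            class = "trial_input")
}

#' Score a network's choice on one trial
#'
#' The chosen channel is the output channel (units 1-2 vs units 3-4) with
#' the larger mean activity over the response epoch. Positive relevant
#' coherence maps to channel 1. An exact tie is flagged ambiguous and
#' counted incorrect.
#'
#' @param z output time series (T x 4), aligned with the trial's epochs.
#' @param spec the [trial_spec()] that produced the trial.
#' @param epoch optional per-step epoch labels; defaults to the spec's.
#' @return list with `chosen_channel` (1, 2 or NA), `correct`, `ambiguous`.
#' @export
score_choice <- function(z, spec, epoch = NULL) {
  if (is.null(epoch)) epoch <- epoch_labels(spec$durations, spec$dt)
  if (nrow(z) != length(epoch)) stop("z does not cover the trial")
  resp <- epoch == "resp"
  if (!any(resp)) stop("no response epoch in trial")
  m1 <- mean(z[resp, 1:2])
  m2 <- mean(z[resp, 3:4])
  if (m1 == m2) {
    return(list(chosen_channel = NA_integer_, correct = FALSE,
                ambiguous = TRUE))
  }
  chosen <- if (m1 > m2) 1L else 2L
  should <- if (relevant_coherence(spec) > 0) 1L else 2L
  list(chosen_channel = chosen, correct = chosen == should, ambiguous = FALSE)
}

#' Canonical condition grid
#'
#' The 16 canonical trial conditions: 2 contexts x 8 relevant coherences.
#'
#' @return data.frame with columns `context` and `coherence`.
#' @export
condition_grid <- function() {
  expand.grid(coherence = coherence_set,
              context = c("color", "motion"),
              KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("context", "coherence")]
}

#' Psychometric curve
#'
#' Fraction of correct choices as a function of the coherence of one
#' modality, within a fixed context. For each requested coherence,
#' `n_trials` noisy trials are simulated with the other modality's coherence
#' drawn at random, and the mean accuracy is reported.
#'
#' @param params network parameters ([rnn_params()]).
#' @param context task context for all trials.
#' @param vary which modality's coherence is swept (`"color"` or
#'   `"motion"`); defaults to the relevant one.
#' @param coherences coherence values to test.
#' @param n_trials trials per coherence value.
#' @return data.frame with columns `coherence`, `p_correct`, `n`.
#' @export
psychometric_curve <- function(params, context = c("color", "motion"),
                               vary = NULL, coherences = coherence_set,
                               n_trials = 50) {
  context <- match.arg(context)
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (is.null(vary)) vary <- context
  vary <- match.arg(vary, c("color", "motion"))
  p_correct <- vapply(coherences, function(co) {
    ok <- vapply(seq_len(n_trials), function(i) {
      c_col <- if (vary == "color") co else sample_coherence()
      c_mot <- if (vary == "motion") co else sample_coherence()
      spec <- trial_spec(context, c_color = c_col, c_motion = c_mot,
                         gamma_bar_color = runif(1, 0.8, 1.2),
                         gamma_bar_motion = runif(1, 0.8, 1.2),
                         dt = params$dt)
      trial <- build_trial(spec, sigma_in = params$sigma_in)
      sim <- simulate_trial(params, trial)
      score_choice(sim$z, spec)$correct
    }, logical(1))
    mean(ok)
  }, numeric(1))
  data.frame(coherence = coherences, p_correct = p_correct, n = n_trials)
}
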