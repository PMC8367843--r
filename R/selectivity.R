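#' Activated units
#'
#' A unit counts as active if its condition-averaged firing rate exceeds
#' `threshold` (default 5 Hz) at any time bin of any condition.
#'
#' @param act an `activity_tensor` of condition-averaged rates.
#' @param threshold activation threshold in Hz.
#' @return integer vector of active unit indices (possibly empty).
#' @export
active_units <- function(act, threshold = 5) {
  peak <- apply(act$rates, 1, max)
  which(peak > threshold)
}

task_variable_levels <- c("color_cue", "motion_cue",
                          "green", "red", "left", "right")

# Epoch-mean response of every unit to each task-variable level, relative
# to its fixation-epoch baseline. Cue levels are measured during the cue
# epoch within the matching context; stimulus levels during the stimulus
# epoch within the matching context, split by relevant-coherence sign
# (positive color coherence = green, positive motion coherence = left).
level_responses <- function(act) {
  fix <- window_bins(act, "fix")
  cue <- window_bins(act, "cue")
  stim <- window_bins(act, "stim")
  base <- apply(act$rates[, , fix, drop = FALSE], 1, mean)
  cond <- act$conditions
  sel <- list(
    color_cue = list(bins = cue, conds = cond$context == "color"),
    motion_cue = list(bins = cue, conds = cond$context == "motion"),
    green = list(bins = stim,
                 conds = cond$context == "color" & cond$coherence > 0),
    red = list(bins = stim,
               conds = cond$context == "color" & cond$coherence < 0),
    left = list(bins = stim,
                conds = cond$context == "motion" & cond$coherence > 0),
    right = list(bins = stim,
                 conds = cond$context == "motion" & cond$coherence < 0))
  resp <- vapply(sel, function(s) {
    apply(act$rates[, s$conds, s$bins, drop = FALSE], 1, mean) - base
  }, numeric(dim(act$rates)[1]))
  resp
}

#' Classify unit selectivity
#'
#' A unit is selective to a task-variable level (color cue, motion cue,
#' green, red, left, right) if its epoch-mean response to that level
#' exceeds its fixation baseline by more than `theta_sel` Hz. Categories
#' follow the mixed-selectivity taxonomy:
#' \itemize{
#'   \item `pure` — exactly one level;
#'   \item `mixed_rule` — both context cues, no stimulus level;
#'   \item `mixed_color` / `mixed_motion` — two or more stimulus levels
#'     but no cue, assigned to the modality with the larger response
#'     difference;
#'   \item `mixed_rule_stim` — at least one cue and one stimulus level;
#'   \item `none` — inactive or no level above threshold.
#' }
#'
#' @param act an `activity_tensor` of condition-averaged rates.
#' @param theta_sel selectivity threshold in Hz.
#' @param threshold activation threshold for [active_units()].
#' @return data.frame, one row per unit: `unit`, `active`, `category`,
#'   logical columns per level, and the six response values.
#' @export
classify_selectivity <- function(act, theta_sel = 2, threshold = 5) {
  n <- dim(act$rates)[1]
  resp <- level_responses(act)
  act_set <- active_units(act, threshold = threshold)
  selective <- resp > theta_sel
  selective[setdiff(seq_len(n), act_set), ] <- FALSE
  category <- vapply(seq_len(n), function(i) {
    s <- task_variable_levels[selective[i, ]]
    has_cue <- any(c("color_cue", "motion_cue") %in% s)
    n_cue <- sum(c("color_cue", "motion_cue") %in% s)
    stim_lv <- intersect(s, c("green", "red", "left", "right"))
    if (length(s) == 0) return("none")
    if (length(s) == 1) return("pure")
    if (has_cue && length(stim_lv) > 0) return("mixed_rule_stim")
    if (n_cue == 2) return("mixed_rule")
    # two or more stimulus levels, no cue: attribute to the modality with
    # the larger absolute response
    col_amp <- max(resp[i, c("green", "red")])
    mot_amp <- max(resp[i, c("left", "right")])
    if (col_amp >= mot_amp) "mixed_color" else "mixed_motion"
  }, character(1))
  out <- data.frame(unit = seq_len(n),
                    active = seq_len(n) %in% act_set,
                    category = category)
  out <- cbind(out, as.data.frame(selective),
               setNames(as.data.frame(resp), paste0("resp_",
                                                    colnames(resp))))
  out
}

#' Selectivity category fractions across models
#'
#' Per-category fraction of active units, averaged over a list of models
#' (or precomputed activity tensors), with the standard error of the mean
#' across models.
#'
#' @param models list of `rnn_params` (simulated on demand) or
#'   `activity_tensor` objects.
#' @param theta_sel,threshold passed to [classify_selectivity()].
#' @param ... further arguments to [condition_activity()] when `models`
#'   contains parameter objects.
#' @return data.frame with `category`, `mean_fraction`, `sem`, plus a row
#'   `active` for the active-unit fraction of all units.
#' @export
selectivity_fractions <- function(models, theta_sel = 2, threshold = 5, ...) {
  if (length(models) < 1) stop("need at least one model")
  cats <- c("pure", "mixed_rule", "mixed_color", "mixed_motion",
            "mixed_rule_stim", "none")
  per_model <- vapply(models, function(m) {
    act <- if (inherits(m, "activity_tensor")) m
           else condition_activity(m, ...)
    lab <- classify_selectivity(act, theta_sel, threshold)
    n_active <- sum(lab$active)
    fr <- if (n_active == 0) rep(0, length(cats)) else
      vapply(cats, function(cc) sum(lab$category == cc & lab$active) /
               n_active, numeric(1))
    c(fr, active = mean(lab$active))
  }, numeric(length(cats) + 1))
  mn <- rowMeans(per_model)
  sem <- if (length(models) > 1) {
    apply(per_model, 1, sd) / sqrt(length(models))
  } else rep(NA_real_, nrow(per_model))
  data.frame(category = c(cats, "active"), mean_fraction = mn, sem = sem,
             row.names = NULL)
}
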