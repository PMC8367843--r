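default_config <- function() {
  list(
    seed = 1,
    out_dir = "rnngeom_run",
    network = list(N = 256, tau = 20, dt = 20,
                   sigma_rec = 0.05, sigma_in = 0.01),
    task = list(durations = as.list(default_durations())),
    training = list(lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                    batch_size = 64, max_steps = 20000,
                    loss_threshold = 0.01, perf_threshold = 0.95,
                    eval_every = 100),
    analysis = list(stages = c("selectivity", "geometry", "popdyn",
                               "attractors", "perturbation"),
                    theta_sel = 2, active_threshold = 5,
                    jpca_k = 6, fp_restarts = 300,
                    perturb_scales = c(0.8, 0.9, 0.95, 1, 1.05, 1.1, 1.2)))
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste(path, k, sep = ".")
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", full, " must be a section")
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys, injects
#' defaults for everything unspecified, and validates basic constraints.
#' An empty file yields the full default configuration (N = 256,
#' tau = dt = 20 ms, sigma_rec = 0.05, sigma_in = 0.01).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`); `NULL` for
#'   pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user) > 0) cfg <- merge_config(cfg, user)
  }
  durs <- unlist(cfg$task$durations)
  if (any(durs < 0)) stop("negative epoch duration in config")
  if (any(durs %% cfg$network$dt != 0)) {
    stop("epoch durations must be divisible by dt")
  }
  if (cfg$network$N < 2) stop("network.N must be at least 2")
  if (cfg$network$tau <= 0 || cfg$network$dt <= 0) {
    stop("tau and dt must be positive")
  }
  cfg
}

#' Save a run configuration
#'
#' @param cfg configuration list.
#' @param path output file (`.yaml` or `.json`).
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' Checkpoints hold all weights, biases and scalar metadata of an
#' [rnn_params()] plus free-form provenance fields (seed, training step).
#'
#' @param params [rnn_params()].
#' @param path file path (`.rds`).
#' @param meta named list of provenance fields.
#' @return the path (save) or the restored `rnn_params` with a `meta`
#'   attribute (load).
#' @export
save_checkpoint <- function(params, path, meta = list()) {
  saveRDS(list(params = unclass(params), meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  p <- ck$params
  params <- rnn_params(p$W_in, p$W_rec, p$W_out, p$b, p$b_out,
                       tau = p$tau, dt = p$dt,
                       sigma_rec = p$sigma_rec, sigma_in = p$sigma_in)
  attr(params, "meta") <- ck$meta
  params
}

#' Build a small trained fixture network
#'
#' Trains a compact network (default N = 32) on the full task until it
#' reaches `perf_target`, retrying with fresh initializations if a seed
#' fails, and caches the condition-averaged activity for all 16
#' conditions. This gives every analysis a realistic trained substrate
#' without a full-size training run.
#'
#' @param seed RNG seed; retries use `seed + 100, seed + 200, ...`.
#' @param N network size.
#' @param perf_target required evaluated performance.
#' @param max_steps per-attempt training step budget.
#' @param retries additional attempts after the first.
#' @return list with `params`, `activity` (noise-free condition-averaged
#'   `activity_tensor`), `curves`, `performance`, `seed_used`.
#' @export
make_fixture <- function(seed = 1, N = 32, perf_target = 0.85,
                         max_steps = 2500, retries = 2) {
  for (attempt in 0:retries) {
    s <- seed + 100 * attempt
    cfg <- train_config(max_steps = max_steps, loss_threshold = 0.008,
                        perf_threshold = perf_target, seed = s)
    fit <- train_rnn(NULL, cfg, N = N)
    perf <- evaluate_performance(fit$params, 512)
    if (perf >= perf_target) {
      act <- condition_activity(fit$params, noise = FALSE)
      return(list(params = fit$params, activity = act,
                  curves = fit$curves, performance = perf,
                  seed_used = s))
    }
  }
  stop("fixture training failed to reach the performance target after ",
       retries + 1, " attempts")
}

#' Run the end-to-end pipeline
#'
#' Executes train -> simulate -> configured analysis stages, writing
#' tables (CSV), a checkpoint and a JSON manifest (inputs, seeds, stage
#' status, output files) into `cfg$out_dir`.
#'
#' @param cfg configuration from [load_config()].
#' @param verbose print stage progress.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   stages = list(), outputs = character(0))
  say <- function(...) if (verbose) message(...)
  durations <- unlist(cfg$task$durations)

  say("training")
  tc <- do.call(train_config, c(cfg$training, list(seed = cfg$seed)))
  set.seed(cfg$seed)
  params0 <- do.call(init_params, cfg$network)
  fit <- train_rnn(params0, tc, durations = durations)
  ck_path <- file.path(cfg$out_dir, "checkpoint.rds")
  save_checkpoint(fit$params, ck_path,
                  meta = list(seed = cfg$seed,
                              steps = max(fit$curves$step),
                              converged = fit$converged))
  curve_path <- file.path(cfg$out_dir, "training_curves.csv")
  write.csv(fit$curves, curve_path, row.names = FALSE)
  manifest$stages$training <- list(status = "ok",
                                   converged = fit$converged)
  manifest$outputs <- c(manifest$outputs, ck_path, curve_path)

  say("simulating condition averages")
  act <- condition_activity(fit$params, noise = FALSE,
                            durations = durations)
  manifest$stages$simulate <- list(status = "ok")

  run_stage <- function(name, fun) {
    if (!name %in% cfg$analysis$stages) return()
    say(name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      manifest$outputs <<- c(manifest$outputs, res)
    }
  }

  run_stage("selectivity", function() {
    lab <- classify_selectivity(act, cfg$analysis$theta_sel,
                                cfg$analysis$active_threshold)
    path <- file.path(cfg$out_dir, "selectivity.csv")
    write.csv(lab, path, row.names = FALSE)
    path
  })
  run_stage("geometry", function() {
    axes <- lapply(c("C-cue", "M-cue", "C-choice", "M-choice"),
                   function(nm) define_task_axis(act, nm))
    names(axes) <- vapply(axes, `[[`, character(1), "name")
    cue_sub <- fit_subspace(epoch_matrix(act, "cue"), k = 2)
    integ3 <- fit_subspace(epoch_matrix(act, "stim"), k = 3)
    plane <- select_integ_plane(integ3, axes[["C-choice"]],
                                axes[["M-choice"]])
    rows <- do.call(rbind, lapply(names(axes), function(nm) {
      data.frame(axis = nm,
                 cue_subspace = axis_subspace_angle(axes[[nm]], cue_sub),
                 integ_subspace = axis_subspace_angle(axes[[nm]],
                                                      plane$basis))
    }))
    path <- file.path(cfg$out_dir, "axis_angles.csv")
    write.csv(rows, path, row.names = FALSE)
    path
  })
  run_stage("popdyn", function() {
    si <- sequentiality_index(act)
    rot <- fit_rotation(act, k = cfg$analysis$jpca_k)
    path <- file.path(cfg$out_dir, "popdyn.csv")
    write.csv(data.frame(si = si$si, entropy = si$entropy,
                         mean_log_ridge = si$mean_log_ridge,
                         jpca_r2 = rot$r2_M,
                         jpca_freq1 = rot$frequencies[1]),
              path, row.names = FALSE)
    path
  })
  run_stage("attractors", function() {
    fp <- condition_attractors(fit$params,
                               n_restarts = cfg$analysis$fp_restarts)
    path <- file.path(cfg$out_dir, "attractors.csv")
    write.csv(fp$table, path, row.names = FALSE)
    path
  })
  run_stage("perturbation", function() {
    rows <- do.call(rbind, lapply(cfg$analysis$perturb_scales,
                                  function(s) {
      pg <- scale_weights(fit$params, s, "global")
      data.frame(scale = s,
                 performance = evaluate_performance(pg$params, 128))
    }))
    path <- file.path(cfg$out_dir, "perturbation.csv")
    write.csv(rows, path, row.names = FALSE)
    path
  })

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
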