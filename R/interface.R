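# Run configuration and the phase-diagram sweep driver. A run configuration
# is a flat named list mirroring every model parameter, schedule field and
# seed; it round-trips losslessly through YAML, so a config file fully
# reproduces a run.

#' Assemble a run configuration
#'
#' @param alpha,beta apical and basal tensions.
#' @param n_cells cell number.
#' @param v_lumen preferred lumen volume; `NULL` means the size-rescaled
#'   value [lumen_target()]`(n_cells)` (100 at the reference 300 cells).
#' @param scheme `"threshold"` or `"fluctuation"`.
#' @param schedule_kind,v0,t_max activity schedule fields.
#' @param t_end protocol duration (`NULL`: `t_max` for active runs, twice
#'   that for passive ones).
#' @param seed integer RNG seed.
#' @param pre_relax initial passive relaxation time.
#' @param snapshot_every,log_every output cadences.
#' @param ... overrides for the remaining [model_params()] fields.
#' @return a `run_config` list.
#' @export
run_config <- function(alpha, beta, n_cells = 300, v_lumen = NULL,
                       scheme = "threshold", schedule_kind = "linear",
                       v0 = 0, t_max = 1000, t_end = NULL, seed = 1,
                       pre_relax = 1, snapshot_every = 10, log_every = 1,
                       ...) {
  if (is.null(v_lumen)) v_lumen <- lumen_target(n_cells)
  structure(list(alpha = alpha, beta = beta, n_cells = n_cells,
                 v_lumen = v_lumen, scheme = scheme,
                 schedule_kind = schedule_kind, v0 = v0, t_max = t_max,
                 t_end = t_end, seed = seed, pre_relax = pre_relax,
                 snapshot_every = snapshot_every, log_every = log_every,
                 extra = list(...)),
            class = "run_config")
}

#' Write or read a run configuration
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns the `run_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$extra)) x$extra <- list()
  structure(x, class = "run_config")
}

#' Execute a run configuration
#'
#' Seeds the shell, builds the parameters and schedule, and calls
#' [run_protocol()].
#'
#' @param config a `run_config`.
#' @return a `shell_trajectory`.
#' @export
run_from_config <- function(config) {
  set.seed(config$seed)
  pars <- do.call(model_params,
                  c(list(alpha = config$alpha, beta = config$beta,
                         v_lumen = config$v_lumen), config$extra))
  mesh <- build_initial_shell(config$n_cells, config$v_lumen)
  sched <- activity_schedule(config$schedule_kind, config$v0, config$t_max)
  run_protocol(mesh, pars, scheme = config$scheme, schedule = sched,
               t_end = config$t_end, pre_relax = config$pre_relax,
               snapshot_every = config$snapshot_every,
               log_every = config$log_every)
}

#' Sweep the (alpha, beta) plane
#'
#' Runs one or more replicates at every grid point, classifies the final
#' shapes, and tabulates the phase diagram. Shells of `n_cells != 300` use
#' the rescaled lumen volume (Eq.-(7)-style matching via [lumen_target()])
#' and the junction-count-rescaled T1 rate [rescale_kt1()], so that the
#' morphology domains are comparable across sizes. A failed run is recorded
#' with an `NA` label and the sweep continues.
#'
#' @param alphas,betas grid coordinates.
#' @param n_cells cell number for every run.
#' @param replicates replicates per grid point (seeds `seed + 0:(r-1)`).
#' @param scheme,schedule activity scheme and 300-cell-reference schedule.
#' @param t_end protocol duration.
#' @param seed base seed.
#' @param config classifier thresholds.
#' @param ... passed to [model_params()].
#' @return data frame with one row per run: `alpha`, `beta`, `replicate`,
#'   `seed`, reduced volume `v`, `delta`, `label`, final `energy`, `n_t1`.
#' @export
sweep_phase_diagram <- function(alphas, betas, n_cells = 300, replicates = 1,
                                scheme = "threshold",
                                schedule = activity_schedule("constant", 0),
                                t_end = NULL, seed = 1,
                                config = morphology_config(), ...) {
  grid <- expand.grid(alpha = alphas, beta = betas)
  v_lum <- lumen_target(n_cells)
  sched <- schedule
  sched$v0 <- if (scheme == "threshold") rescale_kt1(schedule$v0, n_cells)
  else schedule$v0
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      run_seed <- seed + (i - 1) * replicates + (r - 1)
      row <- data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
                        replicate = r, seed = run_seed, v = NA_real_,
                        delta = NA_real_, label = NA_character_,
                        energy = NA_real_, n_t1 = NA_integer_)
      res <- tryCatch({
        set.seed(run_seed)
        pars <- model_params(grid$alpha[i], grid$beta[i], v_lumen = v_lum,
                             ...)
        mesh <- build_initial_shell(n_cells, v_lum)
        tr <- run_protocol(mesh, pars, scheme = scheme, schedule = sched,
                           t_end = t_end, snapshot_every = 0)
        rep <- morphometrics(tr$final, config)
        row$v <- rep$reduced_volume
        row$delta <- rep$delta
        row$label <- rep$morphology
        row$energy <- tail(tr$energy$w, 1)
        row$n_t1 <- tr$n_t1
        row
      }, error = function(e) {
        warning("sweep run (alpha=", grid$alpha[i], ", beta=", grid$beta[i],
                ", rep=", r, ") failed: ", conditionMessage(e), call. = FALSE)
        row
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  do.call(rbind, rows)
}
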