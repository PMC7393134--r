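# Overdamped time integration. Vertices follow dr/dt = -grad w with an
# explicit Euler step of size dt (default 1e-4 tau0); after each move the
# active-rearrangement machinery may initiate T1 transitions. The inner loop
# runs in compiled code and hands control back to R at every step in which a
# T1 is selected or a cell is ready to divide, so all topology edits happen
# in one place; per-step random-draw order is fixed, making trajectories
# independent of chunking and bit-reproducible given the seed.

#' Activity schedule
#'
#' Temporal profile of the activity parameter (the active T1 rate `k_T1` in
#' the threshold scheme, or the tension-fluctuation magnitude `sigma` in the
#' fluctuating-tension scheme): constant, a linear ramp
#' `v0 (t_max - t)/t_max` clipped at zero, or a step profile equal to `v0`
#' for `t < t_max/2` and zero afterwards.
#'
#' @param kind profile type.
#' @param v0 initial activity value (>= 0).
#' @param t_max total protocol duration.
#' @return an `activity_schedule` object.
#' @export
activity_schedule <- function(kind = c("constant", "linear", "step"), v0,
                              t_max = 1000) {
  kind <- match.arg(kind)
  stopifnot(v0 >= 0, t_max > 0)
  structure(list(kind = kind, v0 = v0, t_max = t_max),
            class = "activity_schedule")
}

#' Evaluate an activity schedule
#'
#' @param schedule an `activity_schedule`.
#' @param t time (>= 0).
#' @return the activity level at time `t`; never negative.
#' @export
schedule_value <- function(schedule, t) {
  v <- switch(schedule$kind,
              constant = rep(schedule$v0, length(t)),
              linear = schedule$v0 * (schedule$t_max - t) / schedule$t_max,
              step = ifelse(t < schedule$t_max / 2, schedule$v0, 0))
  pmax(v, 0)
}

schedule_kind_code <- function(schedule) {
  match(schedule$kind, c("constant", "linear", "step")) - 1L
}

#' Rescale the active T1 rate to a different cell number
#'
#' The per-junction flip probability is `k_T1 dt / E`; to keep it fixed when
#' comparing shells of different sizes, `k_T1` is rescaled by the ratio of
#' junction counts, `k_T1 E(N_c) / E(300)` with `E(N) = 3(N - 2)`.
#'
#' @param k_t1 rate calibrated for a 300-cell shell.
#' @param n_cells target cell number.
#' @return the rescaled rate.
#' @export
rescale_kt1 <- function(k_t1, n_cells) {
  k_t1 * (3 * (n_cells - 2)) / (3 * (300 - 2))
}

#' One explicit Euler step of the overdamped dynamics
#'
#' Displaces every vertex by `force * dt` and advances the mesh time. Used
#' for unit-level checks; `run_protocol` runs the same update in compiled
#' code.
#'
#' @param mesh a `shell_mesh`.
#' @param params a `model_params`.
#' @param dt step size (defaults to `params$dt`).
#' @param v_cell_target per-cell target volumes.
#' @return the advanced `shell_mesh`.
#' @export
euler_step <- function(mesh, params, dt = params$dt,
                       v_cell_target = rep(1, length(mesh$cells))) {
  f <- total_force(mesh, params, v_cell_target)
  if (!all(is.finite(f)))
    stop("non-finite force at t = ", mesh$time)
  nv <- nrow(mesh$apical)
  mesh$apical <- mesh$apical + dt * f[seq_len(nv), , drop = FALSE]
  mesh$basal <- mesh$basal + dt * f[nv + seq_len(nv), , drop = FALSE]
  mesh$time <- mesh$time + dt
  mesh
}

scheme_code <- function(scheme) {
  match(scheme, c("none", "threshold", "fluctuation")) - 1L
}

# Chunked driver around cpp_advance: handles rosette dwell bookkeeping,
# T1 initiation/resolution, divisions, snapshots, and logs.
simulate_core <- function(mesh, params, scheme, schedule, total_steps,
                          grow = FALSE, vt = NULL, phase = NULL,
                          snapshot_steps = 0L, log_steps = 0L,
                          scheme_label = scheme, step_offset = 0,
                          init_dwells = list(), init_refr = character(),
                          stop_at_cells = Inf) {
  dt <- params$dt
  dwell_steps <- max(1L, as.integer(round(params$dwell / dt)))
  nc <- length(mesh$cells)
  if (is.null(vt)) vt <- rep(1, nc)
  if (is.null(phase)) phase <- integer(nc)
  sc <- scheme_code(scheme)
  sk <- schedule_kind_code(schedule)
  step <- 0L
  dwells <- init_dwells
  events <- list()
  snapshots <- list()
  elog_t <- numeric()
  elog_w <- numeric()
  n_t1 <- 0L
  div_blocked <- integer()
  # junctions created by a T1 are refractory (no new flip) until they regrow
  # past the scheme's trigger length; tracked by vertex-pair key
  refr_keys <- init_refr
  junction_keys <- function() paste(mesh$junctions[, "u"], mesh$junctions[, "v"])

  eligibility <- function() {
    dc <- unique(unlist(lapply(dwells, function(d) d$cells)))
    t1_legal_all(mesh, dwell_cells = if (is.null(dc)) integer() else dc)
  }
  elig <- eligibility()

  while (step < total_steps) {
    nv <- nrow(mesh$apical)
    glue <- matrix(integer(), 0, 2)
    if (length(dwells) > 0) {
      gl <- lapply(dwells, function(d)
        rbind(c(d$u, d$v), c(d$u + nv, d$v + nv)))
      glue <- do.call(rbind, gl) - 1L
    }
    next_resolve <- if (length(dwells) > 0)
      min(vapply(dwells, function(d) d$resolve_step, numeric(1))) -
      step_offset else Inf
    chunk_end <- min(total_steps, next_resolve)
    if (snapshot_steps > 0) {
      next_snap <- (step %/% snapshot_steps + 1L) * snapshot_steps
      chunk_end <- min(chunk_end, next_snap)
    }
    n_steps <- as.integer(chunk_end - step)
    sel <- integer()
    div_cell <- -1L
    if (n_steps > 0) {
      nc <- length(mesh$cells)
      div_ok <- rep(TRUE, nc)
      dwell_cells <- unique(unlist(lapply(dwells, function(d) d$cells)))
      div_ok[c(div_blocked, dwell_cells)] <- FALSE
      f <- mesh_flat(mesh)
      keys <- junction_keys()
      refr <- keys %in% refr_keys
      res <- cpp_advance(f$pos, f$nv, f$cell_ptr, f$cell_vert, f$junc,
                         params$alpha, params$beta, params$k_cell,
                         params$k_lumen, vt, params$v_lumen, mesh$gamma,
                         dt, step_offset + step, n_steps, sc, sk, schedule$v0,
                         schedule$t_max, params$delta_l, params$trigger_len,
                         params$tau, elig, refr, glue, grow, phase, div_ok,
                         params$tau_d, params$tau_g, grow, log_steps)
      refr_keys <- setdiff(refr_keys, keys[refr & !res$refractory])
      mesh <- mesh_set_pos(mesh, res$pos)
      mesh$gamma <- res$gamma
      vt <- res$v_cell_target
      phase <- res$phase
      if (grow) params$v_lumen <- res$v_lumen_target
      step <- step + res$steps_done
      mesh$time <- (step_offset + step) * dt
      if (nrow(res$energy_log) > 0) {
        elog_t <- c(elog_t, res$energy_log[, 1])
        elog_w <- c(elog_w, res$energy_log[, 2])
      }
      if (res$reason == 3L)
        stop("non-finite energy at t = ", step * dt,
             "; simulation aborted", call. = FALSE)
      if (res$reason == 1L) sel <- res$selected + 1L
      if (res$reason == 2L) div_cell <- res$divide_cell + 1L
    }

    # initiate T1s selected this step (at most one per cell; rosette opens)
    if (length(sel) > 0) {
      busy <- unique(unlist(lapply(dwells, function(d) d$cells)))
      elig_now <- eligibility()
      f <- mesh_flat(mesh)
      mid <- cpp_mid_lengths(f$pos, f$nv, f$junc)
      vcm <- vertex_cells_matrix(mesh$cells, nrow(mesh$apical))
      for (j in sort(sel)) {
        if (!elig_now[j]) next
        u <- unname(mesh$junctions[j, "u"])
        v <- unname(mesh$junctions[j, "v"])
        ab <- mesh$junctions[j, c("cell_uv", "cell_vu")]
        cd <- c(setdiff(vcm[u, ], ab), setdiff(vcm[v, ], ab))
        cells4 <- c(ab[[1]], ab[[2]], cd[1], cd[2])
        if (any(cells4 %in% busy)) next
        e_dir <- mesh$apical[v, ] - mesh$apical[u, ]
        en <- sqrt(sum(e_dir^2))
        e_dir <- if (en > 1e-30) e_dir / en else c(1, 0, 0)
        mid_a <- colMeans(mesh$apical[c(u, v), , drop = FALSE])
        mid_b <- colMeans(mesh$basal[c(u, v), , drop = FALSE])
        mesh$apical[u, ] <- mid_a
        mesh$apical[v, ] <- mid_a
        mesh$basal[u, ] <- mid_b
        mesh$basal[v, ] <- mid_b
        dwells[[length(dwells) + 1]] <- list(
          u = u, v = v, resolve_step = step_offset + step + dwell_steps,
          e_dir = e_dir, cells = cells4)
        busy <- c(busy, cells4)
        events[[length(events) + 1]] <- data.frame(
          time = (step_offset + step) * dt, u = u, v = v, scheme = scheme_label,
          mid_length = mid[j], type = "t1")
        n_t1 <- n_t1 + 1L
      }
      elig <- eligibility()
    }

    # resolve rosettes whose dwell has elapsed
    if (length(dwells) > 0) {
      due <- vapply(dwells, function(d) d$resolve_step <= step_offset + step,
                    logical(1))
      for (d in dwells[due]) {
        jrow <- which(mesh$junctions[, "u"] == min(d$u, d$v) &
                        mesh$junctions[, "v"] == max(d$u, d$v))
        mid_a <- mesh$apical[d$u, ]
        mid_b <- mesh$basal[d$u, ]
        mesh <- t1_swap(mesh, jrow)
        cells4 <- attr(mesh, "t1_cells")
        dir <- t1_separation_dir(mesh, cells4, d$e_dir, mid_a)
        if (!is.null(dir)) {
          s <- 0.5 * params$separation
          mesh$apical[d$u, ] <- mid_a + s * dir
          mesh$apical[d$v, ] <- mid_a - s * dir
          mesh$basal[d$u, ] <- mid_b + s * dir
          mesh$basal[d$v, ] <- mid_b - s * dir
        }
        refr_keys <- union(refr_keys, paste(min(d$u, d$v), max(d$u, d$v)))
        div_blocked <- integer()  # side counts changed; re-test divisions
      }
      dwells <- dwells[!due]
      elig <- eligibility()
    }

    # division ready: split the cell, or postpone if it is a triangle
    if (div_cell > 0) {
      if (length(mesh$cells[[div_cell]]) < 4) {
        div_blocked <- union(div_blocked, div_cell)
      } else {
        mesh <- divide_cell(mesh, div_cell)
        nc <- length(mesh$cells)
        vt[div_cell] <- 1
        vt <- c(vt, 1)
        phase[div_cell] <- 0L
        phase <- c(phase, 0L)
        div_blocked <- integer()
        events[[length(events) + 1]] <- data.frame(
          time = (step_offset + step) * dt, u = NA_integer_, v = NA_integer_,
          scheme = "division", mid_length = NA_real_, type = "division")
        elig <- eligibility()
        if (length(mesh$cells) >= stop_at_cells) break
      }
    }

    if (snapshot_steps > 0 && step %% snapshot_steps == 0 && step > 0) {
      snapshots[[length(snapshots) + 1]] <- mesh
    }
  }
  list(mesh = mesh, vt = vt, phase = phase, dwells = dwells,
       refr_keys = refr_keys,
       energy = data.frame(t = elog_t, w = elog_w),
       events = if (length(events) > 0) do.call(rbind, events) else
         data.frame(time = numeric(), u = integer(), v = integer(),
                    scheme = character(), mid_length = numeric(),
                    type = character()),
       snapshots = snapshots, n_t1 = n_t1,
       v_lumen = params$v_lumen)
}

#' Run a full simulation protocol
#'
#' Relaxes the shell by overdamped gradient descent while the selected
#' activity scheme initiates T1 rearrangements: either the threshold scheme
#' (junctions shorter than `delta_l` flip with probability one, longer ones
#' at rate `k_T1(t)/E` per junction) or the fluctuating-tension scheme
#' (Ornstein-Uhlenbeck line tensions; a T1 fires when a junction shrinks
#' below the trigger length). Each initiated T1 collapses the edge to its
#' midpoint, holds the four-way rosette for the dwell time, then swaps the
#' connectivity and separates the new vertex pair. An optional initial
#' passive relaxation (activity zero) corrects the seeded cell volumes
#' before activity starts; the protocol clock starts after it.
#'
#' @param mesh initial `shell_mesh` (e.g. from [build_initial_shell()]).
#' @param params a `model_params`.
#' @param scheme `"threshold"` or `"fluctuation"`.
#' @param schedule an [activity_schedule()] for `k_T1` (threshold) or
#'   `sigma` (fluctuation). Default: no activity.
#' @param t_end protocol duration; defaults to `schedule$t_max` for active
#'   runs and twice that for passive runs (stomatocytes develop slowly).
#' @param pre_relax duration of the initial passive relaxation (default 1).
#' @param snapshot_every snapshot cadence in time units (0 = none).
#' @param log_every energy-log cadence in time units.
#' @param seed optional integer seed set before the run.
#' @return a `shell_trajectory`: list with the `final` mesh, `snapshots`,
#'   `energy` log, T1/division `events`, `n_t1`, and the inputs.
#' @export
run_protocol <- function(mesh, params, scheme = c("threshold", "fluctuation"),
                         schedule = activity_schedule("constant", 0),
                         t_end = NULL, pre_relax = 1, snapshot_every = 10,
                         log_every = 1, seed = NULL, resume = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_end))
    t_end <- if (schedule$v0 > 0) schedule$t_max else 2 * schedule$t_max
  dt <- params$dt
  if (pre_relax > 0) {
    quiet <- activity_schedule("constant", 0, t_max = max(pre_relax, 1))
    pre <- simulate_core(mesh, params, scheme, quiet,
                         total_steps = as.integer(round(pre_relax / dt)),
                         log_steps = 0L, scheme_label = "pre_relax")
    mesh <- pre$mesh
    mesh$time <- 0
  }
  log_steps <- if (log_every > 0) as.integer(round(log_every / dt)) else 0L
  snap_steps <- if (snapshot_every > 0)
    as.integer(round(snapshot_every / dt)) else 0L
  res <- simulate_core(mesh, params, scheme, schedule,
                       total_steps = as.integer(round(t_end / dt)),
                       snapshot_steps = snap_steps, log_steps = log_steps,
                       scheme_label = scheme,
                       step_offset = if (is.null(resume)) 0
                       else as.integer(round(mesh$time / dt)),
                       init_dwells = if (is.null(resume)) list()
                       else resume$dwells,
                       init_refr = if (is.null(resume)) character()
                       else resume$refr_keys)
  structure(list(final = res$mesh, snapshots = res$snapshots,
                 energy = res$energy, events = res$events, n_t1 = res$n_t1,
                 params = params, scheme = scheme, schedule = schedule,
                 t_end = t_end,
                 state = res[c("dwells", "refr_keys", "vt", "phase")]),
            class = "shell_trajectory")
}

#' @export
print.shell_trajectory <- function(x, ...) {
  cat(sprintf(
    "<shell_trajectory> %d cells, t_end=%g, %d T1 events, final energy %.4f\n",
    length(x$final$cells), x$t_end, x$n_t1,
    if (nrow(x$energy) > 0) tail(x$energy$w, 1) else NA_real_))
  invisible(x)
}

#' Relax a shell passively
#'
#' Convenience wrapper: runs the threshold scheme with zero active rate
#' (short junctions below `delta_l` may still flip) for time `t_end`.
#'
#' @inheritParams run_protocol
#' @return a `shell_trajectory`.
#' @export
relax_shell <- function(mesh, params, t_end, snapshot_every = 0,
                        log_every = 1, seed = NULL) {
  run_protocol(mesh, params, scheme = "threshold",
               schedule = activity_schedule("constant", 0, t_max = t_end),
               t_end = t_end, pre_relax = 0,
               snapshot_every = snapshot_every, log_every = log_every,
               seed = seed)
}
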