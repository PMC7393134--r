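# Stochastic cell growth and division. Quiescent cells enter a growth
# period at constant probability 1/tau_d per unit time; a growing cell's
# target volume increases linearly at rate 1/tau_g and the cell divides as
# soon as it doubles, with the mitotic plane connecting a random pair of
# opposing lateral sides. In growing shells the preferred lumen volume
# follows the rescaling relation with the cell number replaced by the total
# target volume of the tissue.

#' Preferred lumen volume for a given tissue size
#'
#' Solves `(v + n)^(1/3) - v^(1/3) = 400^(1/3) - 100^(1/3)` for `v` by
#' bisection, anchored at the reference shell of 300 cells with lumen volume
#' 100. The condition keeps the spherical-shape threshold in `(alpha, beta)`
#' the same across shell sizes: a spherical shell of equilibrium cell height
#' around the lumen then reaches its cell number at the same tissue tension.
#' `n` is the cell number, or the total tissue target volume in growing
#' shells.
#'
#' @param n cell number or total tissue volume (> 0).
#' @return the preferred lumen volume; strictly increasing in `n`, with
#'   `lumen_target(300) = 100`. Below `n` of about 21 (where even a vanishing
#'   lumen cannot reach the reference shell thickness) the solution is 0.
#' @export
lumen_target <- function(n) {
  stopifnot(all(n > 0))
  vapply(n, cpp_lumen_target, numeric(1))
}

#' One stochastic growth step
#'
#' Each quiescent cell enters growth with probability `dt/tau_d`; each
#' growing cell's target volume increases by `dt/tau_g`, and cells reaching
#' a target of 2 are divided immediately (triangular cells wait for a T1 to
#' give them at least 4 sides). Provided for unit-level checks; protocols
#' run the same update inside the compiled loop.
#'
#' @param state list with `mesh`, integer `phase` (0 quiescent, 1 growing)
#'   and numeric `v_target` per cell.
#' @param params a `model_params`.
#' @param dt step size (defaults to `params$dt`).
#' @return the updated state (possibly with one more cell).
#' @export
growth_step <- function(state, params, dt = params$dt) {
  nc <- length(state$mesh$cells)
  stopifnot(length(state$phase) == nc, length(state$v_target) == nc)
  enter <- state$phase == 0L & runif(nc) < dt / params$tau_d
  state$phase[enter] <- 1L
  growing <- state$phase == 1L
  state$v_target[growing] <- pmin(2, state$v_target[growing] +
                                    dt / params$tau_g)
  ready <- which(state$v_target >= 2)
  for (c in ready) {
    if (length(state$mesh$cells[[c]]) < 4) next  # postpone triangles
    state$mesh <- divide_cell(state$mesh, c)
    state$v_target[c] <- 1
    state$v_target <- c(state$v_target, 1)
    state$phase[c] <- 0L
    state$phase <- c(state$phase, 0L)
  }
  state
}

#' Divide a cell across a random pair of opposing lateral sides
#'
#' Picks a side uniformly at random and pairs it with the (near-)opposite
#' side `i + floor(n/2)`; a new vertex is inserted at the midpoint of each
#' chosen apical edge (and of its basal partner), and a new junction
#' connecting the two midpoints splits the cell in two. The division adds
#' one cell, two vertices per surface, and three junctions, preserving the
#' Euler relation; the daughter is appended as the last cell.
#'
#' @param mesh a `shell_mesh`.
#' @param cell index of the cell to divide (must have >= 4 sides).
#' @param side optional side index (1..n) overriding the random choice.
#' @return the mesh with `N_c + 1` cells.
#' @export
divide_cell <- function(mesh, cell, side = NULL) {
  f0 <- mesh$cells[[cell]]
  n <- length(f0)
  if (n < 4) stop("cannot divide a triangular cell (", cell, ")")
  i <- if (is.null(side)) sample.int(n, 1) else side
  j <- (i - 1 + n %/% 2) %% n + 1
  nv <- nrow(mesh$apical)
  w1 <- nv + 1L
  w2 <- nv + 2L
  ends <- function(k) c(f0[k], f0[k %% n + 1])
  e1 <- ends(i)
  e2 <- ends(j)
  mesh$apical <- rbind(mesh$apical, colMeans(mesh$apical[e1, , drop = FALSE]),
                       colMeans(mesh$apical[e2, , drop = FALSE]))
  mesh$basal <- rbind(mesh$basal, colMeans(mesh$basal[e1, , drop = FALSE]),
                      colMeans(mesh$basal[e2, , drop = FALSE]))
  # walk the parent boundary inserting the midpoints, then split at them
  with_mid <- integer()
  for (k in seq_len(n)) {
    with_mid <- c(with_mid, f0[k])
    if (k == i) with_mid <- c(with_mid, w1)
    if (k == j) with_mid <- c(with_mid, w2)
  }
  p1 <- which(with_mid == w1)
  p2 <- which(with_mid == w2)
  seg <- function(a, b) {  # cyclic slice from position a to b inclusive
    m <- length(with_mid)
    if (a <= b) with_mid[a:b] else c(with_mid[a:m], with_mid[1:b])
  }
  d1 <- seg(p1, p2)
  d2 <- seg(p2, p1)
  cells <- mesh$cells
  cells[[cell]] <- d1
  cells[[length(cells) + 1]] <- d2
  # the neighbours across the two split sides gain the midpoint vertex
  nb1 <- other_cell_of_edge(mesh$junctions, e1[1], e1[2], cell)
  nb2 <- other_cell_of_edge(mesh$junctions, e2[1], e2[2], cell)
  for (spec in list(list(nb = nb1, e = e1, w = w1),
                    list(nb = nb2, e = e2, w = w2))) {
    fb <- cells[[spec$nb]]
    # neighbour traverses the edge in the opposite direction
    pos <- which(fb == spec$e[2])
    succ <- fb[pos %% length(fb) + 1]
    stopifnot(succ == spec$e[1])
    cells[[spec$nb]] <- append(fb, spec$w, after = pos)
  }
  newj <- build_junctions(cells)
  old_keys <- paste(mesh$junctions[, "u"], mesh$junctions[, "v"])
  new_keys <- paste(newj[, "u"], newj[, "v"])
  gamma <- mesh$gamma[match(new_keys, old_keys)]
  split_parent <- function(w) if (w == w1) e1 else e2
  for (k in which(is.na(gamma))) {
    p <- newj[k, c("u", "v")]
    if (all(p %in% c(w1, w2))) {
      gamma[k] <- 0  # the new daughter-daughter junction
    } else {
      w <- p[p %in% c(w1, w2)]
      parent_edge <- split_parent(w)
      gamma[k] <- mesh$gamma[match(paste(min(parent_edge), max(parent_edge)),
                                   old_keys)]
    }
  }
  mesh$cells <- cells
  mesh$junctions <- newj
  mesh$gamma <- gamma
  mesh
}

#' Grow a shell from one cell number to another
#'
#' Runs the overdamped dynamics with stochastic growth and division active:
#' quiescent cells enter growth at rate `1/tau_d`, growing cells double
#' their target volume over `tau_g` and divide, and the preferred lumen
#' volume tracks the total tissue target volume through [lumen_target()].
#' An active T1 schedule may run on top (its rate is rescaled to the
#' starting cell number via [rescale_kt1()] when `rescale = TRUE`).
#'
#' @param alpha,beta apical and basal tensions.
#' @param n_start,n_end starting and final cell numbers.
#' @param schedule optional [activity_schedule()] for the threshold T1 rate.
#' @param rescale rescale the schedule's rate from the 300-cell reference to
#'   `n_start` junction counts.
#' @param params optional `model_params`; defaults to the reference settings
#'   with `v_lumen = lumen_target(n_start)`.
#' @param t_max_steps hard cap on integration steps (guards runaway runs).
#' @param pre_relax initial passive relaxation time.
#' @param seed optional RNG seed.
#' @param snapshot_every,log_every output cadences in time units.
#' @return a `shell_trajectory` whose final mesh has `n_end` cells (or the
#'   state at the step cap).
#' @export
run_growth_protocol <- function(alpha, beta, n_start = 100, n_end = 300,
                                schedule = NULL, rescale = TRUE,
                                params = NULL, t_max_steps = 5e7,
                                pre_relax = 1, seed = NULL,
                                snapshot_every = 0, log_every = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params))
    params <- model_params(alpha, beta, v_lumen = lumen_target(n_start))
  mesh <- build_initial_shell(n_start, params$v_lumen)
  if (pre_relax > 0) {
    quiet <- activity_schedule("constant", 0, t_max = max(pre_relax, 1))
    pre <- simulate_core(mesh, params, "threshold", quiet,
                         total_steps = as.integer(round(pre_relax / params$dt)))
    mesh <- pre$mesh
    mesh$time <- 0
  }
  if (is.null(schedule)) {
    schedule <- activity_schedule("constant", 0, t_max = 1000)
  } else if (rescale) {
    schedule$v0 <- rescale_kt1(schedule$v0, n_start)
  }
  dt <- params$dt
  log_steps <- if (log_every > 0) as.integer(round(log_every / dt)) else 0L
  snap_steps <- if (snapshot_every > 0)
    as.integer(round(snapshot_every / dt)) else 0L
  vt <- rep(1, length(mesh$cells))
  phase <- integer(length(mesh$cells))
  dwells <- list()
  refr <- character()
  energy <- list()
  events <- list()
  snaps <- list()
  n_t1 <- 0L
  steps_done <- 0
  block <- as.integer(round(10 / dt))  # advance in blocks of 10 time units
  while (length(mesh$cells) < n_end && steps_done < t_max_steps) {
    res <- simulate_core(mesh, params, "threshold", schedule,
                         total_steps = block, grow = TRUE, vt = vt,
                         phase = phase, snapshot_steps = snap_steps,
                         log_steps = log_steps, step_offset = steps_done,
                         init_dwells = dwells, init_refr = refr,
                         stop_at_cells = n_end)
    if (nrow(res$energy) > 0) energy[[length(energy) + 1]] <- res$energy
    if (nrow(res$events) > 0) events[[length(events) + 1]] <- res$events
    snaps <- c(snaps, res$snapshots)
    mesh <- res$mesh
    vt <- res$vt
    phase <- res$phase
    dwells <- res$dwells
    refr <- res$refr_keys
    params$v_lumen <- res$v_lumen
    n_t1 <- n_t1 + res$n_t1
    steps_done <- steps_done + block
    mesh$time <- steps_done * dt
  }
  structure(list(final = mesh, snapshots = snaps,
                 energy = if (length(energy) > 0) do.call(rbind, energy)
                 else data.frame(t = numeric(), w = numeric()),
                 events = if (length(events) > 0) do.call(rbind, events)
                 else data.frame(),
                 n_t1 = n_t1, params = params, scheme = "growth",
                 schedule = schedule, t_end = steps_done * dt,
                 v_target = vt, phase = phase,
                 state = list(dwells = dwells, refr_keys = refr, vt = vt,
                              phase = phase)),
            class = "shell_trajectory")
}
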