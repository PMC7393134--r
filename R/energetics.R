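# Energy terms and forces. The shell energy (in units of Gamma_l *
# V_cell^(2/3), with Gamma_l the lateral tension) is
#   w = sum_cells [ alpha a_a + beta a_b + (1/2) a_l ]
# plus harmonic volume constraints (K/2)(V - V_target)^2 for each cell and
# the lumen, plus the fluctuating line-tension term sum_j gamma_j (l_a + l_b).
# The R implementations here are written against the plain-R polygon
# primitives; the compiled core evaluates the same expressions with analytic
# gradients and is cross-checked against these (and against finite
# differences) in the tests.

#' Model parameters of the epithelial shell
#'
#' All quantities are dimensionless: lengths in units of V_cell^(1/3),
#' tensions in units of the lateral tension Gamma_l, time in units of
#' tau0 = 1/(Gamma_l mu) with mu the vertex mobility.
#'
#' @param alpha apical surface tension.
#' @param beta basal surface tension.
#' @param v_lumen target lumen volume (units of cell volume).
#' @param k_cell,k_lumen moduli of the harmonic volume constraints
#'   (default 100, large enough to hold volumes within about 1 percent).
#' @param dt integration time step (default 1e-4).
#' @param delta_l threshold junction mid-length for the threshold T1 scheme
#'   (default 0.15, roughly a quarter to a third of the mean junction length).
#' @param trigger_len junction mid-length below which a T1 is initiated in
#'   the fluctuating-tension scheme (default 0.01).
#' @param tau time scale of the Ornstein-Uhlenbeck tension process
#'   (default 1).
#' @param dwell duration of the four-way rosette before a T1 is resolved
#'   (default 2e-3).
#' @param separation distance by which the new vertex pair is separated when
#'   a rosette is resolved (default 5e-4).
#' @param tau_d expected time until a quiescent cell enters growth
#'   (default 2000).
#' @param tau_g duration of the linear volume-doubling growth phase
#'   (default 1).
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha, beta, v_lumen = 100, k_cell = 100,
                         k_lumen = 100, dt = 1e-4, delta_l = 0.15,
                         trigger_len = 0.01, tau = 1, dwell = 2e-3,
                         separation = 5e-4, tau_d = 2000, tau_g = 1) {
  stopifnot(k_cell > 0, k_lumen > 0, v_lumen > 0, dt > 0, delta_l >= 0,
            trigger_len >= 0, tau > 0, dwell >= 0, separation >= 0,
            tau_d > 0, tau_g > 0)
  structure(list(alpha = alpha, beta = beta, v_lumen = v_lumen,
                 k_cell = k_cell, k_lumen = k_lumen, dt = dt,
                 delta_l = delta_l, trigger_len = trigger_len, tau = tau,
                 dwell = dwell, separation = separation, tau_d = tau_d,
                 tau_g = tau_g), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> alpha=%g beta=%g v_lumen=%g K=(%g,%g) dt=%g\n",
    x$alpha, x$beta, x$v_lumen, x$k_cell, x$k_lumen, x$dt))
  invisible(x)
}

#' Surface energy of the shell
#'
#' Sum over cells of `alpha a_a + beta a_b + a_l / 2`; each lateral face is
#' shared by two cells, so across a closed shell every junction's quad is
#' counted exactly once.
#'
#' @param mesh a `shell_mesh`.
#' @param params a `model_params`.
#' @return surface energy (units Gamma_l V_cell^(2/3)).
#' @export
surface_energy <- function(mesh, params) {
  w <- 0
  for (c in seq_along(mesh$cells)) {
    ids <- mesh$cells[[c]]
    a_l <- 0
    n <- length(ids)
    for (k in seq_len(n)) {
      u <- ids[k]
      v <- ids[if (k == n) 1 else k + 1]
      a_l <- a_l + polygon_area(lateral_quad(mesh, u, v))
    }
    w <- w + params$alpha * polygon_area(face_points(mesh, ids, "apical")) +
      params$beta * polygon_area(face_points(mesh, ids, "basal")) + a_l / 2
  }
  w
}

#' Harmonic volume-constraint energy
#'
#' `(K_cell/2) sum_i (V_i - V_target_i)^2 + (K_lumen/2)(V_lumen -
#' v_lumen)^2`. Cell and lumen incompressibility are enforced by these
#' auxiliary terms with large moduli rather than exactly.
#'
#' @param mesh a `shell_mesh`.
#' @param params a `model_params`.
#' @param v_cell_target per-cell target volumes (default 1; growing cells
#'   carry larger targets).
#' @return constraint energy.
#' @export
constraint_energy <- function(mesh, params,
                              v_cell_target = rep(1, length(mesh$cells))) {
  vc <- vapply(seq_along(mesh$cells), function(i) cell_volume(mesh, i),
               numeric(1))
  0.5 * params$k_cell * sum((vc - v_cell_target)^2) +
    0.5 * params$k_lumen * (lumen_volume(mesh) - params$v_lumen)^2
}

#' Junctional line-tension energy
#'
#' `sum_j gamma_j (l_aj + l_bj)` over all junctions, with `gamma_j` the
#' fluctuating line tension applied equally to the apical and basal edge of
#' junction j.
#'
#' @param mesh a `shell_mesh` (its `gamma` field holds the tensions).
#' @param params a `model_params` (unused; kept for a uniform signature).
#' @return line-tension energy.
#' @export
line_tension_energy <- function(mesh, params = NULL) {
  if (all(mesh$gamma == 0)) return(0)
  la <- sqrt(rowSums((mesh$apical[mesh$junctions[, "u"], , drop = FALSE] -
                      mesh$apical[mesh$junctions[, "v"], , drop = FALSE])^2))
  lb <- sqrt(rowSums((mesh$basal[mesh$junctions[, "u"], , drop = FALSE] -
                      mesh$basal[mesh$junctions[, "v"], , drop = FALSE])^2))
  sum(mesh$gamma * (la + lb))
}

#' Total energy of the shell
#'
#' Surface + constraint + line-tension energy, evaluated by the compiled
#' core.
#'
#' @inheritParams constraint_energy
#' @return list with `energy` and the components `w_surface`,
#'   `w_constraint`, `w_line`.
#' @export
total_energy <- function(mesh, params,
                         v_cell_target = rep(1, length(mesh$cells))) {
  f <- mesh_flat(mesh)
  r <- cpp_energy_force(f$pos, f$nv, f$cell_ptr, f$cell_vert, f$junc,
                        params$alpha, params$beta, params$k_cell,
                        params$k_lumen, v_cell_target, params$v_lumen,
                        mesh$gamma, want_force = FALSE)
  r[c("energy", "w_surface", "w_constraint", "w_line")]
}

#' Per-vertex forces
#'
#' The exact negative gradient of the total energy with respect to every
#' apical and basal vertex position, computed analytically from the
#' triangulated-geometry formulas (finite differences of the energy remain
#' as the independent check in the tests).
#'
#' @inheritParams constraint_energy
#' @return a (2V x 3) matrix: apical vertex rows first, then basal.
#' @export
total_force <- function(mesh, params,
                        v_cell_target = rep(1, length(mesh$cells))) {
  f <- mesh_flat(mesh)
  r <- cpp_energy_force(f$pos, f$nv, f$cell_ptr, f$cell_vert, f$junc,
                        params$alpha, params$beta, params$k_cell,
                        params$k_lumen, v_cell_target, params$v_lumen,
                        mesh$gamma, want_force = TRUE)
  r$force
}
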