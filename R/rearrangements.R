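# T1 rearrangements. A T1 swaps the four cells arranged around a lateral
# face: the apical edge (u, v) shared by cells A and B collapses, and a new
# edge between the two cells C and D that previously met the edge only at its
# endpoints opens up. The apical network is edited first and the basal
# network and lateral faces follow, since the two networks share one
# topology. During dynamics the collapsed four-way rosette is held for a
# short dwell before being resolved (see `run_protocol`); `apply_t1` performs
# the full collapse-swap-separate move in one call.

# vertex -> incident cells map (each apical vertex is 3-valent)
vertex_cells_map <- function(cells) {
  nv <- max(unlist(cells))
  out <- vector("list", nv)
  for (c in seq_along(cells)) for (v in cells[[c]]) out[[v]] <- c(out[[v]], c)
  out
}

# the cell on the other side of apical edge (u, v) from `cell`
other_cell_of_edge <- function(junctions, u, v, cell) {
  a <- min(u, v)
  b <- max(u, v)
  row <- which(junctions[, "u"] == a & junctions[, "v"] == b)
  cc <- junctions[row, c("cell_uv", "cell_vu")]
  cc[cc != cell][1]
}

# gaining cells (C at u, D at v) of junction j; NA if degenerate
t1_gaining_cells <- function(mesh, j, vmap = NULL) {
  if (is.null(vmap)) vmap <- vertex_cells_map(mesh$cells)
  u <- mesh$junctions[j, "u"]
  v <- mesh$junctions[j, "v"]
  ab <- mesh$junctions[j, c("cell_uv", "cell_vu")]
  C <- setdiff(vmap[[u]], ab)
  D <- setdiff(vmap[[v]], ab)
  if (length(C) != 1 || length(D) != 1) return(c(NA_integer_, NA_integer_))
  c(C, D)
}

#' Is a T1 transition on this junction topologically legal?
#'
#' A flip is refused if either losing cell is a triangle (the flip would
#' create a 2-gon), if the two gaining cells coincide or are already
#' neighbours across another junction (the flip would duplicate an
#' adjacency), or if the junction is currently held in a rosette dwell.
#'
#' @param mesh a `shell_mesh`.
#' @param junction junction index.
#' @param dwell_cells optional integer vector of cells currently involved in
#'   an unresolved rosette; their junctions are blocked.
#' @return `TRUE` if the flip may be applied.
#' @export
t1_legal <- function(mesh, junction, dwell_cells = integer()) {
  t1_legal_all(mesh, dwell_cells)[junction]
}

# vertex -> incident cells as a (nv x 3) matrix (3-valent mesh)
vertex_cells_matrix <- function(cells, nv) {
  vert <- unlist(cells)
  cell <- rep(seq_along(cells), lengths(cells))
  o <- order(vert)
  matrix(cell[o], nrow = nv, ncol = 3, byrow = TRUE)
}

# vectorised legality for all junctions
t1_legal_all <- function(mesh, dwell_cells = integer()) {
  nv <- nrow(mesh$apical)
  sizes <- lengths(mesh$cells)
  J <- mesh$junctions
  A <- J[, "cell_uv"]
  B <- J[, "cell_vu"]
  M <- vertex_cells_matrix(mesh$cells, nv)
  pick_third <- function(vv) {
    cand <- M[vv, , drop = FALSE]
    third <- ifelse(cand[, 1] != A & cand[, 1] != B, cand[, 1],
                    ifelse(cand[, 2] != A & cand[, 2] != B, cand[, 2],
                           cand[, 3]))
    # a vertex whose three cells are not {A, B, other} is degenerate
    ok3 <- (cand[, 1] == A | cand[, 1] == B | cand[, 1] == third) &
      (cand[, 2] == A | cand[, 2] == B | cand[, 2] == third) &
      (cand[, 3] == A | cand[, 3] == B | cand[, 3] == third) &
      third != A & third != B
    list(third = third, ok = ok3)
  }
  cu <- pick_third(J[, "u"])
  cv <- pick_third(J[, "v"])
  C <- cu$third
  D <- cv$third
  nc <- length(mesh$cells)
  enc <- function(a, b) pmin(a, b) * (nc + 1) + pmax(a, b)
  adj <- enc(A, B)
  ok <- sizes[A] > 3 & sizes[B] > 3 & cu$ok & cv$ok & C != D &
    is.na(match(enc(C, D), adj))
  if (length(dwell_cells) > 0)
    ok <- ok & !(A %in% dwell_cells) & !(B %in% dwell_cells) &
      !(C %in% dwell_cells) & !(D %in% dwell_cells)
  ok
}

# insert value `x` into cyclic list `f` directly after (or before) `anchor`
cyclic_insert <- function(f, anchor, x, after = TRUE) {
  i <- which(f == anchor)
  x <- unname(x)
  if (after) append(f, x, after = i) else append(f, x, after = i - 1)
}

# Connectivity part of the T1: edit the cell faces, rebuild the junction
# table, and remap per-junction tensions (the flipped junction starts fresh
# at gamma = 0). Returns the mesh plus the four involved cells.
t1_swap <- function(mesh, j) {
  u <- unname(mesh$junctions[j, "u"])
  v <- unname(mesh$junctions[j, "v"])
  A <- unname(mesh$junctions[j, "cell_uv"])
  B <- unname(mesh$junctions[j, "cell_vu"])
  CD <- t1_gaining_cells(mesh, j)
  C <- CD[1]
  D <- CD[2]
  if (is.na(C) || C == D)
    stop("illegal T1 on junction ", j, ": degenerate gaining cells")
  cells <- mesh$cells
  cells[[A]] <- cells[[A]][cells[[A]] != v]
  cells[[B]] <- cells[[B]][cells[[B]] != u]
  # C keeps u and gains v on u's B-facing side
  fc <- cells[[C]]
  succ <- fc[which(fc == u) %% length(fc) + 1]
  oc <- other_cell_of_edge(mesh$junctions, u, succ, C)
  cells[[C]] <- cyclic_insert(fc, u, v, after = (oc == B))
  # D keeps v and gains u on v's A-facing side
  fd <- cells[[D]]
  succ_d <- fd[which(fd == v) %% length(fd) + 1]
  oc2 <- other_cell_of_edge(mesh$junctions, v, succ_d, D)
  cells[[D]] <- cyclic_insert(fd, v, u, after = (oc2 == A))

  newj <- build_junctions(cells)
  old_keys <- paste(mesh$junctions[, "u"], mesh$junctions[, "v"])
  new_keys <- paste(newj[, "u"], newj[, "v"])
  gamma <- mesh$gamma[match(new_keys, old_keys)]
  # renamed junctions (one endpoint of the flipped edge handed over)
  miss <- which(is.na(gamma))
  for (k in miss) {
    p <- newj[k, c("u", "v")]
    old_p <- ifelse(p == u, v, ifelse(p == v, u, p))
    gamma[k] <- mesh$gamma[match(paste(min(old_p), max(old_p)), old_keys)]
  }
  gamma[new_keys == paste(min(u, v), max(u, v))] <- 0
  mesh$cells <- cells
  mesh$junctions <- newj
  mesh$gamma <- gamma
  attr(mesh, "t1_cells") <- c(A = A, B = B, C = C, D = D)
  mesh
}

# separation direction for the resolved pair: perpendicular to the old edge
# within the local tangent plane, signed so u moves toward the losing cell
# that retained it
t1_separation_dir <- function(mesh, cellsABCD, e_dir, mid) {
  n <- c(0, 0, 0)
  for (c in cellsABCD)
    n <- n + polygon_normal(mesh$apical[mesh$cells[[c]], , drop = FALSE])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-30) n <- mid / sqrt(sum(mid^2)) else n <- n / nn
  d <- c(n[2] * e_dir[3] - n[3] * e_dir[2],
         n[3] * e_dir[1] - n[1] * e_dir[3],
         n[1] * e_dir[2] - n[2] * e_dir[1])
  dn <- sqrt(sum(d^2))
  if (dn < 1e-30) return(NULL)
  d <- d / dn
  gA <- colMeans(mesh$apical[mesh$cells[[cellsABCD[1]]], , drop = FALSE])
  if (sum(d * (gA - mid)) < 0) d <- -d
  d
}

#' Apply a T1 transition to a junction
#'
#' Performs the full mechanical move in one call: the apical (and basal)
#' vertex pair is collapsed to its midpoint, the connectivity of the four
#' surrounding cells is swapped, and the new vertex pair is separated
#' symmetrically by `params$separation` perpendicular to the collapsed edge
#' within the local tangent plane. The per-junction tension of the new
#' junction is reset to 0. During time integration `run_protocol` inserts
#' the rosette dwell between collapse and resolution instead of calling
#' this directly.
#'
#' @param mesh a `shell_mesh`.
#' @param junction junction index.
#' @param params a `model_params` (supplies the separation distance).
#' @return the rearranged `shell_mesh`.
#' @export
apply_t1 <- function(mesh, junction, params = NULL) {
  if (!t1_legal(mesh, junction))
    stop("T1 transition on junction ", junction, " is not legal")
  sep <- if (is.null(params)) 5e-4 else params$separation
  u <- mesh$junctions[junction, "u"]
  v <- mesh$junctions[junction, "v"]
  e_dir <- mesh$apical[v, ] - mesh$apical[u, ]
  en <- sqrt(sum(e_dir^2))
  e_dir <- if (en > 1e-30) e_dir / en else c(1, 0, 0)
  mid_a <- colMeans(mesh$apical[c(u, v), , drop = FALSE])
  mid_b <- colMeans(mesh$basal[c(u, v), , drop = FALSE])
  mesh$apical[u, ] <- mid_a
  mesh$apical[v, ] <- mid_a
  mesh$basal[u, ] <- mid_b
  mesh$basal[v, ] <- mid_b
  mesh <- t1_swap(mesh, junction)
  cellsABCD <- attr(mesh, "t1_cells")
  d <- t1_separation_dir(mesh, cellsABCD, e_dir, mid_a)
  if (!is.null(d)) {
    mesh$apical[u, ] <- mid_a + 0.5 * sep * d
    mesh$apical[v, ] <- mid_a - 0.5 * sep * d
    mesh$basal[u, ] <- mid_b + 0.5 * sep * d
    mesh$basal[v, ] <- mid_b - 0.5 * sep * d
  }
  mesh
}

#' Draw the junctions attempting a T1 under the threshold scheme
#'
#' Every junction whose projected mid-length `(l_a + l_b)/2` is below the
#' threshold `delta_l` attempts the transition with probability one; each
#' longer junction attempts independently with probability
#' `k_t1 * dt / E`, where E is the junction count. Attempts on
#' topologically illegal junctions are discarded.
#'
#' @param mesh a `shell_mesh`.
#' @param k_t1 current active T1 rate (units 1/tau0).
#' @param params a `model_params`.
#' @return integer vector of junction indices selected this step.
#' @export
active_t1_attempts <- function(mesh, k_t1, params) {
  f <- mesh_flat(mesh)
  mid <- cpp_mid_lengths(f$pos, f$nv, f$junc)
  ne <- length(mid)
  sel <- mid < params$delta_l
  if (k_t1 > 0)
    sel <- sel | (runif(ne) < k_t1 * params$dt / ne & mid >= params$delta_l)
  which(sel & t1_legal_all(mesh))
}

#' Junctions triggering a T1 under the fluctuating-tension scheme
#'
#' In the Ornstein-Uhlenbeck line-tension scheme a T1 is only initiated when
#' a junction's mid-length falls below the trigger length (default 0.01).
#'
#' @param mesh a `shell_mesh`.
#' @param params a `model_params`.
#' @return integer vector of junction indices to flip.
#' @export
fluctuation_t1_trigger <- function(mesh, params) {
  f <- mesh_flat(mesh)
  mid <- cpp_mid_lengths(f$pos, f$nv, f$junc)
  which(mid < params$trigger_len & t1_legal_all(mesh))
}

#' One Euler-Maruyama update of the Ornstein-Uhlenbeck junction tensions
#'
#' `gamma <- gamma (1 - dt/tau) + N(0,1) sqrt(2 sigma^2 dt / tau)`, noise
#' independent across junctions; the stationary variance of the process is
#' `sigma^2` and its mean reverts to zero on time scale `tau`.
#'
#' @param gamma numeric vector of current tensions.
#' @param tau relaxation time of the process.
#' @param sigma long-time standard deviation of the tension.
#' @param dt time step.
#' @return updated tension vector.
#' @export
ou_update <- function(gamma, tau, sigma, dt) {
  gamma * (1 - dt / tau) + rnorm(length(gamma)) * sqrt(2 * sigma^2 * dt / tau)
}
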