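# Initial spherical shells: cells are the dual tiling of the convex hull of
# a (locally) minimal-energy Thomson configuration of N_c points on the unit
# sphere, so every apical vertex is 3-valent by construction.

#' Thomson-problem point configuration on the unit sphere
#'
#' Finds a local minimum of the Coulomb energy sum(1/|p_i - p_j|) of n unit
#' charges constrained to the unit sphere, by BFGS on unconstrained
#' coordinates with radial projection folded into the objective. Several
#' random restarts are taken and the lowest-energy solution returned; any
#' local minimum whose hull dual is 3-valent is an acceptable seed packing,
#' since junctional activity randomises the packing anyway.
#'
#' @param n number of points (>= 4).
#' @param restarts number of random restarts.
#' @param maxit BFGS iteration cap per restart.
#' @return n x 3 matrix of unit vectors, deterministic given the RNG state.
#' @export
thomson_points <- function(n, restarts = 3, maxit = 500) {
  stopifnot(n >= 4)
  energy <- function(x) {
    p <- matrix(x, ncol = 3)
    p <- p / sqrt(rowSums(p^2))
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    sum(1 / d) / 2
  }
  grad <- function(x) {
    xm <- matrix(x, ncol = 3)
    r <- sqrt(rowSums(xm^2))
    p <- xm / r
    g <- matrix(0, n, 3)
    for (d in 1:3) {
      dif <- outer(p[, d], p[, d], "-")
      dst <- as.matrix(stats::dist(p))
      diag(dst) <- Inf
      g[, d] <- -rowSums(dif / dst^3)
    }
    # project out the radial component, then chain through the normalisation
    radial <- rowSums(g * p)
    g <- (g - radial * p) / r
    as.numeric(g)
  }
  best <- NULL
  best_e <- Inf
  for (r in seq_len(restarts)) {
    x0 <- rnorm(3 * n)
    fit <- stats::optim(x0, energy, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    if (fit$value < best_e) {
      best_e <- fit$value
      best <- fit$par
    }
  }
  p <- matrix(best, ncol = 3)
  p / sqrt(rowSums(p^2))
}

# Dual of the convex hull of points on the unit sphere: one cell per point,
# one 3-valent apical vertex per hull triangle (at its normalised centroid),
# the triangles around each point ordered counterclockwise seen from outside.
hull_dual <- function(pts, max_tries = 10) {
  n <- nrow(pts)
  for (try in seq_len(max_tries)) {
    jit <- pts + 1e-8 * matrix(rnorm(3 * n), n, 3)
    tri <- cpp_convex_hull(jit) + 1L
    if (length(unique(as.integer(tri))) == n) {
      centroids <- (jit[tri[, 1], ] + jit[tri[, 2], ] + jit[tri[, 3], ]) / 3
      centroids <- centroids / sqrt(rowSums(centroids^2))
      cells <- vector("list", n)
      for (c in seq_len(n)) {
        inc <- which(tri[, 1] == c | tri[, 2] == c | tri[, 3] == c)
        p <- pts[c, ]
        e1 <- if (abs(p[3]) < 0.9) c(-p[2], p[1], 0) else c(0, -p[3], p[2])
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(p[2] * e1[3] - p[3] * e1[2],
                p[3] * e1[1] - p[1] * e1[3],
                p[1] * e1[2] - p[2] * e1[1])
        rel <- sweep(centroids[inc, , drop = FALSE], 2, p)
        ang <- atan2(rel %*% e2, rel %*% e1)
        cells[[c]] <- inc[order(ang)]
      }
      return(list(vertices = centroids, cells = cells))
    }
  }
  stop("degenerate convex hull: could not recover all ", n, " dual cells")
}

#' Build an initial spherical shell
#'
#' Apical vertices are the Thomson-dual tiling scaled so the apical surface
#' encloses exactly `v_lumen`; basal vertices are displaced radially outward
#' by `(3 (v_lumen + n_cells) / 4 pi)^(1/3) - (3 v_lumen / 4 pi)^(1/3)`, the
#' thickness of a spherical shell of `n_cells` unit-volume cells around that
#' lumen. Cell volumes then deviate from 1 by a few percent; protocols
#' correct this with a brief passive relaxation before activity starts.
#'
#' @param n_cells number of cells (>= 12).
#' @param v_lumen target lumen volume in units of cell volume.
#' @return a `shell_mesh`.
#' @export
build_initial_shell <- function(n_cells, v_lumen = 100) {
  stopifnot(n_cells >= 12, v_lumen > 0)
  pts <- thomson_points(n_cells)
  dual <- hull_dual(pts)
  mesh0 <- shell_mesh(dual$vertices, dual$vertices, dual$cells)
  vol1 <- lumen_volume(mesh0)
  orient <- 1
  if (vol1 < 0) {  # flip orientation so apical faces point away from the lumen
    dual$cells <- lapply(dual$cells, rev)
    vol1 <- -vol1
  }
  s <- (v_lumen / vol1)^(1 / 3)
  apical <- dual$vertices * s
  offset <- (3 * (v_lumen + n_cells) / (4 * pi))^(1 / 3) -
    (3 * v_lumen / (4 * pi))^(1 / 3)
  rad <- sqrt(rowSums(apical^2))
  basal <- apical * (1 + offset / rad)
  shell_mesh(apical, basal, dual$cells)
}

#' Deterministic small shells for tests and fixtures
#'
#' * `"dodecahedron"`: 12 pentagonal cells (the dual of the icosahedron),
#'   scaled to enclose `v_lumen`.
#' * `"small_thomson_dual"`: a Thomson-dual shell with `n_cells` cells.
#' * `"concentric_spheres"`: apical surface on a sphere of radius `r_in`,
#'   basal on radius `r_out` (same tiling), a per-cell curvature fixture.
#'
#' @param kind fixture name.
#' @param n_cells cells for `"small_thomson_dual"` / `"concentric_spheres"`.
#' @param v_lumen lumen volume for the volume-scaled fixtures.
#' @param r_in,r_out radii for `"concentric_spheres"`.
#' @return a `shell_mesh`.
#' @export
fixture_shell <- function(kind = c("dodecahedron", "small_thomson_dual",
                                   "concentric_spheres"),
                          n_cells = 32, v_lumen = NULL, r_in = 2.879,
                          r_out = 4.573) {
  kind <- match.arg(kind)
  if (kind == "dodecahedron") {
    phi <- (1 + sqrt(5)) / 2
    ico <- rbind(
      cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
      cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
      cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
    ico <- ico / sqrt(rowSums(ico^2))
    dual <- hull_dual(ico)
    if (is.null(v_lumen)) v_lumen <- 12
    mesh0 <- shell_mesh(dual$vertices, dual$vertices, dual$cells)
    v0 <- lumen_volume(mesh0)
    if (v0 < 0) {
      dual$cells <- lapply(dual$cells, rev)
      v0 <- -v0
    }
    s <- (v_lumen / v0)^(1 / 3)
    apical <- dual$vertices * s
    offset <- (3 * (v_lumen + 12) / (4 * pi))^(1 / 3) -
      (3 * v_lumen / (4 * pi))^(1 / 3)
    basal <- apical * (1 + offset / sqrt(rowSums(apical^2)))
    shell_mesh(apical, basal, dual$cells)
  } else if (kind == "small_thomson_dual") {
    if (is.null(v_lumen)) v_lumen <- cpp_lumen_target(n_cells)
    build_initial_shell(n_cells, v_lumen)
  } else {
    pts <- thomson_points(n_cells)
    dual <- hull_dual(pts)
    mesh0 <- shell_mesh(dual$vertices, dual$vertices, dual$cells)
    if (lumen_volume(mesh0) < 0) dual$cells <- lapply(dual$cells, rev)
    shell_mesh(dual$vertices * r_in, dual$vertices * r_out, dual$cells)
  }
}
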