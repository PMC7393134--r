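# Fixtures are built in code, deterministically, and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a single cuboid cell (apical unit square at z = 0, basal at z = h); an open
# mesh without a junction table, usable by the per-cell geometry and energy
# functions
cube_cell_mesh <- function(h = 1, s = 1) {
  apical <- s * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  basal <- apical
  basal[, 3] <- h
  structure(list(apical = apical, basal = basal, cells = list(1:4),
                 junctions = matrix(integer(), 0, 4,
                                    dimnames = list(NULL, c("u", "v",
                                                            "cell_uv",
                                                            "cell_vu"))),
                 gamma = numeric(0), time = 0),
            class = "shell_mesh")
}

# a regular-hexagon prism cell (side s, height h), open like the cube
hex_prism_mesh <- function(s = 1, h = 1) {
  ang <- 2 * pi * (0:5) / 6
  apical <- cbind(s * cos(ang), s * sin(ang), 0)
  basal <- apical
  basal[, 3] <- h
  structure(list(apical = apical, basal = basal, cells = list(1:6),
                 junctions = matrix(integer(), 0, 4,
                                    dimnames = list(NULL, c("u", "v",
                                                            "cell_uv",
                                                            "cell_vu"))),
                 gamma = numeric(0), time = 0),
            class = "shell_mesh")
}

dodeca_shell <- function() cached("dodeca", {
  set.seed(424201)
  fixture_shell("dodecahedron")
})

shell32 <- function() cached("shell32", {
  set.seed(424202)
  fixture_shell("small_thomson_dual", n_cells = 32)
})

shell64 <- function() cached("shell64", {
  set.seed(424203)
  fixture_shell("small_thomson_dual", n_cells = 64)
})

sphere_fixture <- function(n = 200) cached(paste0("sphere", n), {
  set.seed(424204)
  fixture_shell("concentric_spheres", n_cells = n, r_in = 2.879,
                r_out = 4.573)
})

# an open one-face mesh holding an arbitrary planar polygon (for anisometry)
polygon_face_mesh <- function(pts) {
  structure(list(apical = pts, basal = pts, cells = list(seq_len(nrow(pts))),
                 junctions = matrix(integer(), 0, 4,
                                    dimnames = list(NULL, c("u", "v",
                                                            "cell_uv",
                                                            "cell_vu"))),
                 gamma = numeric(0), time = 0),
            class = "shell_mesh")
}

# apply a random rigid motion to every vertex of a mesh
rigid_motion <- function(mesh, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3, sd = 2)
  mesh$apical <- sweep(mesh$apical %*% R, 2, tr, "+")
  mesh$basal <- sweep(mesh$basal %*% R, 2, tr, "+")
  mesh
}
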