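# The shell mesh: paired apical/basal polygonal networks with identical
# topology. Cells are prism-like polyhedra; the cyclic apical vertex list of
# each cell is stored counterclockwise as seen from outside the shell, and
# apical vertex i pairs with basal vertex i.

#' Construct a shell mesh
#'
#' A shell mesh represents a closed single-cell-thick epithelial shell. The
#' apical (lumen-facing) and basal (outer) polygonal networks share one
#' topology: cell faces are cyclic lists of apical vertex indices, ordered
#' counterclockwise as seen from outside the shell, and apical vertex `i`
#' pairs with basal vertex `i`. Lateral faces are the quadrilaterals
#' `(a_u, a_v, b_v, b_u)` spanned by each junction, triangulated (like all
#' faces) by a fan from the vertex centroid. All lengths are expressed in
#' units of the cell volume to the power 1/3.
#'
#' @param apical numeric matrix (V x 3) of apical vertex positions.
#' @param basal numeric matrix (V x 3) of basal vertex positions.
#' @param cells list of integer vectors; cyclic apical vertex indices of each
#'   cell face (1-based).
#' @param gamma optional per-junction line tensions (default 0).
#' @param time simulation time (units of the basic time scale tau0).
#' @return an object of class `shell_mesh` with fields `apical`, `basal`,
#'   `cells`, `junctions` (one row per junction: vertex pair and the two
#'   adjacent cells), `gamma`, and `time`.
#' @export
shell_mesh <- function(apical, basal, cells, gamma = NULL, time = 0) {
  stopifnot(is.matrix(apical), is.matrix(basal), ncol(apical) == 3,
            all(dim(apical) == dim(basal)), is.list(cells))
  cells <- lapply(cells, as.integer)
  junctions <- build_junctions(cells)
  if (is.null(gamma)) gamma <- numeric(nrow(junctions))
  stopifnot(length(gamma) == nrow(junctions))
  structure(list(apical = apical, basal = basal, cells = cells,
                 junctions = junctions, gamma = gamma, time = time),
            class = "shell_mesh")
}

#' @export
print.shell_mesh <- function(x, ...) {
  cat(sprintf(
    "<shell_mesh> %d cells, %d vertices per surface, %d junctions, t = %g\n",
    length(x$cells), nrow(x$apical), nrow(x$junctions), x$time))
  invisible(x)
}

# Junction table from the cell faces. Each undirected apical edge must be
# traversed once in each direction by its two adjacent cells; rows are
# (u, v, cell_uv, cell_vu) with u < v, ordered by (u, v).
build_junctions <- function(cells) {
  cells <- lapply(cells, as.integer)
  from <- unlist(cells, use.names = FALSE)
  to <- unlist(lapply(cells, function(f) c(f[-1], f[1])), use.names = FALSE)
  cell <- rep(seq_along(cells), lengths(cells))
  u <- pmin(from, to)
  v <- pmax(from, to)
  K <- max(v) + 1
  key <- as.numeric(u) * K + v
  # sort by (key, direction): each undirected edge must appear exactly twice,
  # once per direction, so sorted keys pair up as (forward, backward)
  o <- order(key, from > to)
  ks <- key[o]
  n2 <- length(ks)
  if (n2 %% 2 != 0 || any(ks[seq(1, n2, 2)] != ks[seq(2, n2, 2)]) ||
      (n2 > 2 && any(ks[seq(2, n2 - 1, 2)] == ks[seq(3, n2, 2)])))
    stop("edge(s) not shared by exactly two directed traversals")
  fwd <- o[seq(1, n2, 2)]   # traversal with from < to
  bwd <- o[seq(2, n2, 2)]
  if (any(from[fwd] >= to[fwd]) || any(from[bwd] <= to[bwd]))
    stop("inconsistent face orientation at edge ", from[fwd[1]], "-",
         to[fwd[1]])
  rows <- cbind(from[fwd], to[fwd], cell[fwd], cell[bwd])
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  dimnames(rows) <- list(NULL, c("u", "v", "cell_uv", "cell_vu"))
  rows
}

# 0-based flattened topology for the compiled core
mesh_flat <- function(mesh) {
  list(pos = rbind(mesh$apical, mesh$basal),
       nv = nrow(mesh$apical),
       cell_ptr = as.integer(c(0, cumsum(lengths(mesh$cells)))),
       cell_vert = as.integer(unlist(mesh$cells) - 1L),
       junc = matrix(as.integer(mesh$junctions[, 1:4] - 1L), ncol = 4))
}

# write flattened positions (2V x 3) back into a mesh
mesh_set_pos <- function(mesh, pos) {
  nv <- nrow(mesh$apical)
  mesh$apical <- pos[seq_len(nv), , drop = FALSE]
  mesh$basal <- pos[nv + seq_len(nv), , drop = FALSE]
  mesh
}

# cells incident to an apical vertex
cells_at_vertex <- function(cells, v) {
  which(vapply(cells, function(f) any(f == v), logical(1)))
}

#' Validate the structure of a shell mesh
#'
#' Checks the structural invariants of a closed shell: every vertex is
#' 3-valent, every face has at least three vertices, every junction borders
#' exactly two distinct cells, face orientations are globally consistent
#' (each undirected edge is traversed once in each direction), and the Euler
#' relation V - E + N_c = 2 holds, so E = 3(N_c - 2) and V = 2(N_c - 2).
#'
#' @param mesh a `shell_mesh`.
#' @return a list with `ok` (logical), vertex/junction/cell counts,
#'   `euler_ok`, `face_sizes`, and a character vector `problems` naming any
#'   offending elements.
#' @export
validate_mesh <- function(mesh) {
  problems <- character()
  nv <- nrow(mesh$apical)
  nc <- length(mesh$cells)
  if (!all(dim(mesh$apical) == dim(mesh$basal)))
    problems <- c(problems, "apical and basal vertex sets differ in size")
  face_sizes <- lengths(mesh$cells)
  small <- which(face_sizes < 3)
  if (length(small) > 0)
    problems <- c(problems, paste0("face with <3 vertices: cell ",
                                   paste(small, collapse = ", ")))
  valence <- tabulate(unlist(mesh$cells), nbins = nv)
  badv <- which(valence != 3)
  if (length(badv) > 0)
    problems <- c(problems,
                  paste0("vertex ", badv, " has valence ", valence[badv]))
  ne <- tryCatch(nrow(build_junctions(mesh$cells)), error = function(e) {
    problems <<- c(problems, conditionMessage(e))
    NA_integer_
  })
  euler_ok <- !is.na(ne) && (nv - ne + nc == 2)
  if (!is.na(ne) && !euler_ok)
    problems <- c(problems, sprintf("Euler relation violated: V=%d E=%d N=%d",
                                    nv, ne, nc))
  if (!is.na(ne)) {
    same <- which(mesh$junctions[, "cell_uv"] == mesh$junctions[, "cell_vu"])
    if (length(same) > 0)
      problems <- c(problems, paste0("junction ", same,
                                     " borders a single cell"))
  }
  list(ok = length(problems) == 0, n_vertices = nv, n_junctions = ne,
       n_cells = nc, euler_ok = isTRUE(euler_ok), face_sizes = face_sizes,
       problems = problems)
}

face_points <- function(mesh, ids, surface) {
  if (surface == "apical") mesh$apical[ids, , drop = FALSE]
  else mesh$basal[ids, , drop = FALSE]
}

lateral_quad <- function(mesh, u, v) {
  rbind(mesh$apical[u, ], mesh$apical[v, ], mesh$basal[v, ], mesh$basal[u, ])
}

#' Area of one face of a shell mesh
#'
#' @param mesh a `shell_mesh`.
#' @param face cell index (for `"apical"`/`"basal"`) or junction index (for
#'   `"lateral"`).
#' @param surface which face of the cell or junction.
#' @return face area via the centroid-fan triangulation.
#' @export
face_area <- function(mesh, face, surface = c("apical", "basal", "lateral")) {
  surface <- match.arg(surface)
  if (surface == "lateral") {
    j <- mesh$junctions[face, ]
    polygon_area(lateral_quad(mesh, j[["u"]], j[["v"]]))
  } else {
    polygon_area(face_points(mesh, mesh$cells[[face]], surface))
  }
}

#' Volume of one cell
#'
#' Signed volume of the closed prism-like polyhedron bounded by the cell's
#' apical, basal, and lateral faces (divergence theorem over the centroid-fan
#' triangulation); positive for correctly oriented cells, in units of the
#' cell volume.
#'
#' @param mesh a `shell_mesh`.
#' @param cell cell index.
#' @return signed cell volume.
#' @export
cell_volume <- function(mesh, cell) {
  ids <- mesh$cells[[cell]]
  v <- polygon_fan_volume(face_points(mesh, ids, "basal")) -
    polygon_fan_volume(face_points(mesh, ids, "apical"))
  n <- length(ids)
  for (k in seq_len(n)) {
    u <- ids[k]
    w <- ids[if (k == n) 1 else k + 1]
    v <- v + polygon_fan_volume(lateral_quad(mesh, u, w))
  }
  v
}

#' Volume of the lumen
#'
#' Volume enclosed by the apical surface alone, in units of the cell volume.
#'
#' @param mesh a `shell_mesh`.
#' @return enclosed lumen volume.
#' @export
lumen_volume <- function(mesh) {
  sum(vapply(mesh$cells, function(ids)
    polygon_fan_volume(mesh$apical[ids, , drop = FALSE]), numeric(1)))
}

#' Midplane surface of a shell
#'
#' The closed surface whose vertices are the midpoints of corresponding
#' apical/basal vertex pairs, triangulated per cell by a centroid fan. Its
#' area A and enclosed volume V enter the reduced volume v = 6 sqrt(pi) V /
#' A^(3/2).
#'
#' @param mesh a `shell_mesh`.
#' @return list with `area`, `volume`, and the midplane `vertices`.
#' @export
midplane_surface <- function(mesh) {
  mid <- (mesh$apical + mesh$basal) / 2
  a <- 0
  v <- 0
  for (ids in mesh$cells) {
    p <- mid[ids, , drop = FALSE]
    a <- a + polygon_area(p)
    v <- v + polygon_fan_volume(p)
  }
  list(area = a, volume = v, vertices = mid)
}

# igraph of the cell adjacency (cells adjacent iff they share a junction)
cell_adjacency_graph <- function(mesh) {
  igraph::graph_from_edgelist(
    mesh$junctions[, c("cell_uv", "cell_vu"), drop = FALSE], directed = FALSE)
}

#' Topological distance between two cells
#'
#' Length of the shortest path on the cell adjacency graph (cells are
#' adjacent iff they share a junction); d = 1 for nearest neighbours.
#'
#' @param mesh a `shell_mesh`.
#' @param cell_a,cell_b cell indices.
#' @return non-negative integer distance.
#' @export
topological_distance <- function(mesh, cell_a, cell_b) {
  g <- cell_adjacency_graph(mesh)
  as.integer(igraph::distances(g, v = cell_a, to = cell_b))
}

#' Screen a shell for self-overlap
#'
#' The vertex model has no steric repulsion between cells, so final shapes
#' can self-intersect. This checks whether any two vertex-disjoint triangles
#' of the fan-triangulated apical and basal surfaces intersect; flagged
#' shapes are excluded from morphometric ensembles. Transient overlaps during
#' dynamics are expected and not screened.
#'
#' @param mesh a `shell_mesh`.
#' @param shrink factor by which each triangle is shrunk toward its centroid
#'   before testing (default 0.95): grazing contact between walls - which the
#'   model permits, having no steric repulsion - is not reported, a wall
#'   passing through another is.
#' @return `TRUE` if the surface self-overlaps.
#' @export
detect_self_overlap <- function(mesh, shrink = 0.95) {
  f <- mesh_flat(mesh)
  cpp_self_overlap(f$pos, f$nv, f$cell_ptr, f$cell_vert, shrink)
}
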