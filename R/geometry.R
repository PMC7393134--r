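# Pure-R polygon primitives. These mirror the compiled geometry and serve as
# its independent cross-check in the tests; all faces are triangulated by a
# fan from the vertex centroid, so area and volume are smooth in the vertex
# positions and orientation-consistent for non-planar polygons.

#' Area of a (possibly non-planar) polygon
#'
#' Computes the area of the polygon with the given vertices via a triangle
#' fan from the vertex centroid. The result does not depend on orientation
#' and is non-negative; a degenerate polygon (all vertices coincident) has
#' area 0.
#'
#' @param pts numeric matrix (n x 3) of vertex positions in cyclic order.
#' @return polygon area (units of cell volume^(2/3)).
#' @export
polygon_area <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 3, nrow(pts) >= 3)
  g <- colMeans(pts)
  n <- nrow(pts)
  a <- 0
  for (k in seq_len(n)) {
    e1 <- pts[k, ] - g
    e2 <- pts[if (k == n) 1 else k + 1, ] - g
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    a <- a + 0.5 * sqrt(sum(cr^2))
  }
  a
}

# signed volume of the cone from the origin over the centroid-fan of a
# polygon; positive when the stored orientation points away from the origin
polygon_fan_volume <- function(pts) {
  g <- colMeans(pts)
  n <- nrow(pts)
  v <- 0
  for (k in seq_len(n)) {
    a <- pts[k, ]
    b <- pts[if (k == n) 1 else k + 1, ]
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    v <- v + sum(g * cr) / 6
  }
  v
}

# Newell area vector of a polygon (normal with magnitude ~ area, orientation
# following the stored vertex order)
polygon_normal <- function(pts) {
  n <- nrow(pts)
  nv <- c(0, 0, 0)
  for (k in seq_len(n)) {
    a <- pts[k, ]
    b <- pts[if (k == n) 1 else k + 1, ]
    nv <- nv + c(a[2] * b[3] - a[3] * b[2],
                 a[3] * b[1] - a[1] * b[3],
                 a[1] * b[2] - a[2] * b[1])
  }
  nv / 2
}
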