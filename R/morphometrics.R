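# Shape statistics of simulated shells: reduced volume, per-cell height and
# curvature, the thickness-modulation index, h(c) fits and their rescaling
# collapse, topological pair correlations of polygon classes, gyration-tensor
# anisometry, and a heuristic morphology classifier.

#' Reduced volume of a shell
#'
#' `v = 6 sqrt(pi) V / A^(3/2)` evaluated on the midplane surface halfway
#' between the apical and basal sides; `v = 1` for a sphere and decreases as
#' the surface area grows at fixed enclosed volume.
#'
#' @param mesh a `shell_mesh`.
#' @return the reduced volume (0 < v <= 1 for non-self-intersecting shapes).
#' @export
reduced_volume <- function(mesh) {
  mp <- midplane_surface(mesh)
  6 * sqrt(pi) * mp$volume / mp$area^(3 / 2)
}

#' Per-cell height and mean curvature
#'
#' Cell height is the distance between the centroids of the apical and the
#' basal side. The mean curvature of a cell is approximated by that of a
#' truncated cone with the same apical area, basal area, and height:
#' `c = (2/h) (sqrt(a_b) - sqrt(a_a)) / (sqrt(a_b) + sqrt(a_a))`, positive
#' when the basal side is the larger one (outward-bulging cell).
#'
#' @param mesh a `shell_mesh`.
#' @param cells cell indices (default all).
#' @return data frame with columns `cell`, `h`, `c`, `area_apical`,
#'   `area_basal`; `c` is `NA` for degenerate cells with `h = 0`.
#' @export
cell_height_curvature <- function(mesh, cells = seq_along(mesh$cells)) {
  out <- lapply(cells, function(i) {
    ids <- mesh$cells[[i]]
    ga <- colMeans(mesh$apical[ids, , drop = FALSE])
    gb <- colMeans(mesh$basal[ids, , drop = FALSE])
    h <- sqrt(sum((gb - ga)^2))
    aa <- polygon_area(mesh$apical[ids, , drop = FALSE])
    ab <- polygon_area(mesh$basal[ids, , drop = FALSE])
    cc <- if (h > 0) (2 / h) * (sqrt(ab) - sqrt(aa)) / (sqrt(ab) + sqrt(aa))
    else NA_real_
    data.frame(cell = i, h = h, c = cc, area_apical = aa, area_basal = ab)
  })
  do.call(rbind, out)
}

#' Relative thickness-modulation index
#'
#' `delta = p * Dh / hbar`, with `Dh` the amplitude of the thickness
#' modulation (half the full range by default, or half the inter-quantile
#' range for the robust variant), `hbar` the mean cell height, and `p = +1`
#' when per-cell curvature and height are positively correlated (taller
#' cells at the bulges, the hallmark of `alpha > beta`) or `p = -1` when
#' anticorrelated.
#'
#' @param hc data frame from [cell_height_curvature()] (or a mesh).
#' @param robust if `TRUE`, use half the central 95 percent range of `h`
#'   instead of half the full range.
#' @return list with `delta`, `p`, `dh`, `hbar`.
#' @export
thickness_modulation <- function(hc, robust = FALSE) {
  if (inherits(hc, "shell_mesh")) hc <- cell_height_curvature(hc)
  stopifnot(nrow(hc) >= 3)
  h <- hc$h
  cc <- hc$c
  hbar <- mean(h)
  dh <- if (robust)
    diff(stats::quantile(h, c(0.025, 0.975), names = FALSE)) / 2
  else diff(range(h)) / 2
  if (dh == 0 || sd(h) == 0 || sd(cc[!is.na(cc)]) == 0)
    return(list(delta = 0, p = 1, dh = 0, hbar = hbar))
  p <- sign(cor(cc, h, use = "complete.obs"))
  if (p == 0) p <- 1
  list(delta = p * dh / hbar, p = p, dh = dh, hbar = hbar)
}

#' Linear fit of cell height against cell curvature
#'
#' Least-squares line `h = n + k c` across the cells of one shell. Across
#' shells the intercept tracks the flat-epithelium height
#' `(2^(1/3)/3^(1/6))(alpha+beta)^(2/3)` and the slope is approximated by
#' `lambda1 + (alpha-beta) lambda2`.
#'
#' @param hc data frame from [cell_height_curvature()] (or a mesh).
#' @return list with intercept `n`, slope `k`, and the `fit` object;
#'   flagged `degenerate = TRUE` (slope `NA`) if the curvature spread
#'   vanishes.
#' @export
hc_fit <- function(hc) {
  if (inherits(hc, "shell_mesh")) hc <- cell_height_curvature(hc)
  ok <- is.finite(hc$h) & is.finite(hc$c)
  stopifnot(sum(ok) >= 3)
  if (length(unique(hc$c[ok])) < 3 || sd(hc$c[ok]) < 1e-12)
    return(list(n = mean(hc$h[ok]), k = NA_real_, fit = NULL,
                degenerate = TRUE))
  fit <- lm(h ~ c, data = hc[ok, ])
  list(n = unname(coef(fit)[1]), k = unname(coef(fit)[2]), fit = fit,
       degenerate = FALSE)
}

#' Rescale (h, c) pairs onto the common master line
#'
#' `h -> h - (2^(1/3)/3^(1/6))(alpha+beta)^(2/3)` and
#' `c -> [lambda1 + (alpha-beta) lambda2] c`; with the default coefficients
#' the rescaled scatter of shells below the spherical threshold collapses
#' onto the identity line.
#'
#' @param h,c cell heights and curvatures.
#' @param alpha,beta the shell's tensions.
#' @param lambda1,lambda2 collapse coefficients (defaults -0.059 and 0.45).
#' @return data frame with the rescaled `h` and `c`.
#' @export
collapse_transform <- function(h, c, alpha, beta, lambda1 = -0.059,
                               lambda2 = 0.45) {
  data.frame(h = h - (2^(1 / 3) / 3^(1 / 6)) * (alpha + beta)^(2 / 3),
             c = (lambda1 + (alpha - beta) * lambda2) * c)
}

#' Topological pair correlation of a polygon class
#'
#' `g_gamma(d)`: the average number of gamma-sided cells at topological
#' distance d from a gamma-sided cell, `(1/n_gamma) sum_i N_gamma_i(d)` per
#' shell, averaged over the ensemble. For a single shell
#' `sum_d g_gamma(d) = n_gamma - 1`. Shells containing no gamma-gons are
#' omitted (and counted in `n_omitted`).
#'
#' @param meshes a `shell_mesh` or list of them (the ensemble).
#' @param gamma_sides polygon class (5, 6, or 7, say).
#' @param d_max largest distance to tabulate (default: ensemble maximum).
#' @return data frame with `d`, `g` (ensemble mean), `sd`, `n_shells`, and
#'   attribute `n_omitted`.
#' @export
pair_correlation <- function(meshes, gamma_sides, d_max = NULL) {
  if (inherits(meshes, "shell_mesh")) meshes <- list(meshes)
  per_shell <- list()
  omitted <- 0L
  for (mesh in meshes) {
    sizes <- lengths(mesh$cells)
    sel <- which(sizes == gamma_sides)
    if (length(sel) == 0) {
      omitted <- omitted + 1L
      next
    }
    g <- cell_adjacency_graph(mesh)
    dm <- igraph::distances(g, v = sel, to = sel)
    dd <- dm[upper.tri(dm)]
    if (length(dd) == 0) dd <- numeric(0)
    mx <- max(1, dd, na.rm = TRUE)
    tab <- tabulate(dd, nbins = mx)
    per_shell[[length(per_shell) + 1]] <- 2 * tab / length(sel)
  }
  if (length(per_shell) == 0)
    stop("no shell in the ensemble contains a ", gamma_sides, "-gon")
  mx <- if (is.null(d_max)) max(lengths(per_shell)) else d_max
  mat <- t(vapply(per_shell, function(x) {
    length(x) <- mx
    x[is.na(x)] <- 0
    x
  }, numeric(mx)))
  out <- data.frame(d = seq_len(mx), g = colMeans(mat),
                    sd = apply(mat, 2, sd), n_shells = nrow(mat))
  attr(out, "n_omitted") <- omitted
  out
}

#' Anisometry of a cell side
#'
#' Diagonalises the gyration tensor of the face's vertices about their
#' centroid; the anisometry is `kappa = (g1 - g2)/(g1 + g2)` with `g1 >= g2`
#' the two largest eigenvalues (0 for an isometric face, approaching 1 for
#' an elongated one; the third eigenvalue is small but non-zero for the
#' slightly non-planar faces). The long axis is the leading eigenvector.
#'
#' @param mesh a `shell_mesh`.
#' @param cell cell index.
#' @param surface `"apical"` or `"basal"`.
#' @return list with `kappa`, `long_axis`, and the `eigenvalues`.
#' @export
anisometry <- function(mesh, cell, surface = c("apical", "basal")) {
  surface <- match.arg(surface)
  p <- face_points(mesh, mesh$cells[[cell]], surface)
  p <- sweep(p, 2, colMeans(p))
  gyr <- crossprod(p) / nrow(p)
  e <- eigen(gyr, symmetric = TRUE)
  list(kappa = (e$values[1] - e$values[2]) / (e$values[1] + e$values[2]),
       long_axis = e$vectors[, 1], eigenvalues = e$values)
}

#' Thresholds for the morphology classifier
#'
#' The four morphologies are separated by the reduced volume and by how
#' strongly and where the per-cell curvature deviates from that of the
#' equivalent sphere (radius set by the midplane volume). All thresholds are
#' calibration constants fixed against the reference parameter sets of the
#' four morphologies; the boundaries between classes are intrinsically soft
#' (shapes near them are `"hybrid"`).
#'
#' @param v_spherical reduced volume above which a shell is spherical.
#' @param inv_curvature how far below minus this factor times the
#'   equivalent-sphere curvature a cell must curve inward to count as part
#'   of an invagination.
#' @param min_invagination_cells smallest connected inward-curved cluster
#'   that marks a stomatocyte (scattered saddle cells between branches do
#'   not form such clusters).
#' @param lobe_curvature factor over the equivalent-sphere curvature that
#'   marks protruding (lobe) cells.
#' @param min_lobe_cells smallest cell count of a counted lobe.
#' @param branch_lobes smallest number of lobes of a branched shape.
#' @return list of thresholds.
#' @export
morphology_config <- function(v_spherical = 0.925, inv_curvature = 0.3,
                              min_invagination_cells = 3,
                              lobe_curvature = 1.45, min_lobe_cells = 3,
                              branch_lobes = 3) {
  list(v_spherical = v_spherical, inv_curvature = inv_curvature,
       min_invagination_cells = min_invagination_cells,
       lobe_curvature = lobe_curvature, min_lobe_cells = min_lobe_cells,
       branch_lobes = branch_lobes)
}

#' Classify the morphology of a final shape
#'
#' Heuristic operationalisation of the by-eye classes: `"nonphysical"` if
#' the surface self-overlaps; `"spherical"` if the reduced volume exceeds
#' its threshold; `"stomatocyte"` if a sizable connected group of cells
#' curves inward (negative truncated-cone curvature); otherwise lobes are
#' counted as connected groups of strongly outward-curved cells on the cell
#' adjacency graph - few lobes give `"budded"`, several give `"branched"`,
#' and shapes with neither clear feature are `"hybrid"`.
#'
#' @param mesh a `shell_mesh` (a final, overlap-checked snapshot).
#' @param config thresholds from [morphology_config()].
#' @return a character label.
#' @export
classify_morphology <- function(mesh, config = morphology_config()) {
  if (detect_self_overlap(mesh)) return("nonphysical")
  v <- reduced_volume(mesh)
  if (v > config$v_spherical) return("spherical")
  hc <- cell_height_curvature(mesh)
  mp <- midplane_surface(mesh)
  c_sphere <- (4 * pi / (3 * mp$volume))^(1 / 3)  # 1/R of equivalent sphere
  g <- cell_adjacency_graph(mesh)
  # invagination: a connected patch of strongly inward-curved cells
  inv_cells <- which(hc$c < -config$inv_curvature * c_sphere)
  inv_patch <- 0L
  if (length(inv_cells) > 0)
    inv_patch <- max(igraph::components(
      igraph::induced_subgraph(g, inv_cells))$csize)
  lobe_cells <- which(hc$c > config$lobe_curvature * c_sphere)
  n_lobes <- 0L
  if (length(lobe_cells) > 0) {
    sub <- igraph::induced_subgraph(g, lobe_cells)
    comp <- igraph::components(sub)
    n_lobes <- sum(comp$csize >= config$min_lobe_cells)
  }
  if (inv_patch >= config$min_invagination_cells) return("stomatocyte")
  if (n_lobes >= config$branch_lobes) return("branched")
  if (n_lobes >= 1) return("budded")
  "hybrid"
}

#' Full morphometric report of a shell
#'
#' Bundles the reduced volume, the per-cell (h, c) table, the
#' thickness-modulation index, the h(c) line fit, polygon-class counts, and
#' the morphology label into one report.
#'
#' @param mesh a `shell_mesh`.
#' @param config classifier thresholds.
#' @return a `morphometrics_report` list.
#' @export
morphometrics <- function(mesh, config = morphology_config()) {
  hc <- cell_height_curvature(mesh)
  tm <- thickness_modulation(hc)
  fit <- hc_fit(hc)
  sizes <- lengths(mesh$cells)
  structure(list(
    reduced_volume = reduced_volume(mesh),
    cells = hc,
    delta = tm$delta, p = tm$p, h_mean = tm$hbar,
    fit_n = fit$n, fit_k = fit$k,
    polygon_counts = table(factor(sizes, levels = seq(3, max(sizes)))),
    self_overlap = detect_self_overlap(mesh),
    morphology = classify_morphology(mesh, config)),
    class = "morphometrics_report")
}

#' @export
print.morphometrics_report <- function(x, ...) {
  cat(sprintf(
    "<morphometrics> %s: v=%.3f delta=%+.3f h=%.3f (n=%.3f k=%s)%s\n",
    x$morphology, x$reduced_volume, x$delta, x$h_mean, x$fit_n,
    ifelse(is.na(x$fit_k), "NA", sprintf("%.3f", x$fit_k)),
    if (x$self_overlap) " [self-overlap]" else ""))
  invisible(x)
}
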