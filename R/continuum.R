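# Continuum elasticity of the cell sheet. Coarse-graining the cell-level
# surface energy over truncated-pyramid cells gives an energy per unit
# midplane area in which tissue tension (alpha + beta), an
# activity-independent stiffness, a local bending term with spontaneous
# curvature c0 = 2 sqrt(h) (alpha - beta), and a Gaussian term all depend on
# the local thickness h. The flat-epithelium equilibrium and the resulting
# reduced-volume prediction follow from it in closed form.

#' Continuum energy density of the cell sheet
#'
#' Energy per unit midplane area of a patch with thickness `h` and principal
#' curvatures `c1`, `c2`:
#' \deqn{(\alpha+\beta) + 2[1 - (\alpha-\beta)^2/4]\sqrt{h^3}
#'   + \frac{\sqrt h}{8}[c_1 + c_2 - 2\sqrt h(\alpha-\beta)]^2
#'   + \left(\frac{\alpha+\beta}{4} + \frac{\sqrt{h^3}}{12}
#'   - \frac{1}{4\sqrt{h^3}}\right) h^2 c_1 c_2.}
#' The first two terms are the surface tension, the third the local bending
#' energy (modulus sqrt(h)/8, spontaneous curvature 2 sqrt(h)(alpha-beta)),
#' the fourth the Gaussian bending energy. Symmetric under c1 <-> c2.
#'
#' @param h local tissue thickness (> 0), units V_cell^(1/3).
#' @param c1,c2 principal curvatures of the midplane, units V_cell^(-1/3).
#' @param alpha,beta apical and basal tensions.
#' @return energy per unit midplane area.
#' @export
energy_density <- function(h, c1, c2, alpha, beta) {
  stopifnot(all(h > 0))
  sum_t <- alpha + beta
  dif_t <- alpha - beta
  sh <- sqrt(h)
  sh3 <- sqrt(h^3)
  sum_t + 2 * (1 - dif_t^2 / 4) * sh3 +
    (sh / 8) * (c1 + c2 - 2 * sh * dif_t)^2 +
    (sum_t / 4 + sh3 / 12 - 1 / (4 * sh3)) * h^2 * c1 * c2
}

#' Flat-epithelium equilibrium height and area
#'
#' Force balance along the cell height for a flat sheet of identical
#' incompressible hexagonal cells (1 = h a) gives
#' `h0 = (2^(1/3)/3^(1/6)) (alpha+beta)^(2/3)` and `a0 = 1/h0`: tissues
#' under higher tension are taller and narrower (columnar), low-tension
#' tissues squamous.
#'
#' @param tissue_tension `alpha + beta` (> 0); vectorised.
#' @return list with `h0` and `a0` (`h0 * a0 = 1`).
#' @export
flat_equilibrium <- function(tissue_tension) {
  stopifnot(all(tissue_tension > 0))
  h0 <- (2^(1 / 3) / 3^(1 / 6)) * tissue_tension^(2 / 3)
  list(h0 = h0, a0 = 1 / h0)
}

#' Predicted reduced volume of a closed shell
#'
#' Estimating the shell midplane area as `N_c a0` with `a0` the
#' flat-epithelium cell area yields the linear-in-tension prediction
#' `v = 2^(3/2) 3^(3/4) sqrt(pi) v_midplane (alpha+beta) / N_c^(3/2)`;
#' it applies below the spherical threshold where the preferred area, not
#' the enclosed volume, sets the midplane.
#'
#' @param alpha,beta apical and basal tensions.
#' @param n_cells cell number (default 300).
#' @param v_midplane volume enclosed by the midplane surface, units
#'   V_cell; the default 223 is the simulation average for the reference
#'   300-cell shells.
#' @return predicted reduced volume.
#' @export
predicted_reduced_volume <- function(alpha, beta, n_cells = 300,
                                     v_midplane = 223) {
  stopifnot(all(n_cells > 0), all(v_midplane > 0))
  2^(3 / 2) * 3^(3 / 4) * sqrt(pi) * v_midplane * (alpha + beta) /
    n_cells^(3 / 2)
}

#' Spontaneous curvature of the cell sheet
#'
#' `c0 = 2 sqrt(h) (alpha - beta)`: apico-basal differential tension acts as
#' a spontaneous curvature, positive (evaginations, buds) for alpha > beta
#' and negative (invaginations, stomatocytes) for alpha < beta.
#'
#' @param h local tissue thickness (> 0).
#' @param alpha,beta apical and basal tensions.
#' @return spontaneous curvature.
#' @export
spontaneous_curvature <- function(h, alpha, beta) {
  stopifnot(all(h > 0))
  2 * sqrt(h) * (alpha - beta)
}
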