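---
title: "An active 3D vertex model of epithelial shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active 3D vertex model of epithelial shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivertex)
```

## The model

`epivertex` simulates closed, single-cell-thick epithelial shells enclosing
an incompressible fluid lumen. Cells are prism-like polyhedra with polygonal
apical (lumen-facing) and basal (outer) sides and quadrilateral lateral
sides; the apical and basal polygonal networks share one topology, and every
vertex is 3-valent. All quantities are dimensionless: lengths in units of
$V_\mathrm{cell}^{1/3}$, tensions in units of the lateral tension
$\Gamma_\mathrm{l}$, time in units of $\tau_0 = (\Gamma_\mathrm{l}\mu)^{-1}$
with $\mu$ the vertex mobility (which only sets the clock and never appears
separately).

The mechanics is pure surface tension. Summed over the $N_\mathrm{c}$ cells,

$$w \;=\; \sum_{i=1}^{N_\mathrm{c}}
  \Bigl[\alpha\,a^{(i)}_\mathrm{a} + \beta\,a^{(i)}_\mathrm{b}
        + \tfrac12\,a^{(i)}_\mathrm{l}\Bigr],$$

with $\alpha$ and $\beta$ the dimensionless apical and basal tensions and
the $\tfrac12$ reflecting that each lateral face is shared by two cells.
There is deliberately no apical perimeter (acto-myosin cable) term and no
steric repulsion between cells. Cell and lumen incompressibility are
enforced softly, by harmonic terms $\tfrac{K}{2}(V-V_\mathrm{target})^2$
with modulus $K = 100$ for every cell (target 1) and for the lumen (target
$v_\mathrm{lumen}$). Vertices follow the overdamped equation of motion
$\dot{\mathbf r}_j = -\nabla_j w$, integrated with an explicit Euler step
$\delta t = 10^{-4}$.

Two parameters organise the morphology space: the tissue tension
$\alpha+\beta$, which sets the preferred cell height (columnar at high
tension, squamous at low tension) and thereby the preferred shell area, and
the differential tension $\alpha-\beta$, which acts as a spontaneous
curvature (buds for $\alpha>\beta$, invaginations for $\alpha<\beta$).
When the preferred area exceeds the area of the sphere enclosing the fixed
volumes, the shell buckles into stomatocyte, budded, or - with enough
junctional activity - branched shapes.

## Active rearrangements

Cells exchange neighbours through T1 transitions on the cell-cell junctions.
A junction is treated as an edge of the projected mid-length
$(l_\mathrm{a}+l_\mathrm{b})/2$. Two activity schemes are implemented:

* **Threshold scheme.** Junctions shorter than $\delta l = 0.15$ flip with
  probability one; each longer junction flips with probability
  $k_\mathrm{T1}\,\delta t/\mathcal{E}$ per step, where $\mathcal{E}$ is the
  junction count. $k_\mathrm{T1}(t)$ follows an activity schedule (constant,
  linear ramp to zero over $t_\mathrm{max}$, or a step profile).
* **Fluctuating-tension scheme.** Each junction carries a line tension
  $\gamma_i(t)$ obeying an Ornstein-Uhlenbeck process
  $\dot\gamma_i = -\gamma_i/\tau + \xi_i$ with $\tau = 1$ and stationary
  variance $\sigma^2$, adding $w_\gamma = \sum_i \gamma_i
  (l_{\mathrm{a}i}+l_{\mathrm{b}i})$ to the energy. A T1 fires only when a
  junction's mid-length drops below 0.01.

The mechanical move itself collapses the apical (and basal) vertex pair to
its midpoint, holds the four-way rosette for a dwell of $2\times10^{-3}$
time units (the two vertices move jointly under the mean of their forces),
then swaps the connectivity of the four surrounding cells and separates the
new pair by 0.0005, perpendicular to the collapsed edge within the local
tangent plane.

Three behavioural rules are this package's own choices where the procedure
above is under-determined:

* **Refractory regrowth.** A junction created by a T1 is 0.0005 long -
  far below both trigger lengths - so it would flip straight back, forever.
  A new junction is therefore refractory until its mid-length has first
  regrown past its scheme's trigger length ($\delta l$ in the threshold
  scheme, 0.01 in the fluctuating scheme). Without some such rule the
  printed scheme does not terminate.
* **One T1 per cell per step**, and no T1s on the four cells around an
  unresolved rosette: conflicting simultaneous edits of one cell's boundary
  are never attempted.
* **Legality.** A flip is refused when a losing cell is a triangle (a 2-gon
  would result) or when the two gaining cells are already neighbours (a
  duplicated adjacency would result).

## Seeding, growth, and size rescaling

Initial shells are the dual of the convex hull of a (locally optimal)
Thomson configuration of $N_\mathrm{c}$ points on the sphere: one cell per
point, one 3-valent apical vertex per hull triangle, placed at the
normalised triangle centroid (circumcentres would also do; the activity
randomises the packing anyway). The apical surface is scaled to enclose
exactly $v_\mathrm{lumen}$ and the basal vertices sit radially outward by
$[3(v_\mathrm{lumen}+N_\mathrm{c})/4\pi]^{1/3} -
[3 v_\mathrm{lumen}/4\pi]^{1/3}$. Seeded cell volumes are off by up to a
few tens of percent for small shells; a short passive relaxation (default
$t = 1$) corrects them before activity starts. At modulus $K = 100$ the
relaxed volumes still sit a few percent off target - the harmonic constraint
balances the surface pressure at deviation $\sim p/K$ - which is the
expected behaviour of the soft constraint, not an integration error.

In growing shells, quiescent cells enter a growth phase with probability
$\delta t/\tau_\mathrm{d}$ per step ($\tau_\mathrm{d} = 2000$), a growing
cell's target volume rises linearly at rate $1/\tau_\mathrm{g}$
($\tau_\mathrm{g} = 1$), and on doubling the cell divides across a random
pair of opposing lateral sides: a vertex is inserted at the midpoint of each
chosen side and a new junction connects them. For an $n$-gon this yields two
$(\lfloor n/2\rfloor + 2)$-gons - pentagons from a hexagon; triangles
postpone division until a T1 gives them a fourth side.

Comparisons across shell sizes rescale two quantities: the active rate,
$k_\mathrm{T1} \to k_\mathrm{T1}\,\mathcal{E}_{N}/\mathcal{E}_{300}$, so
each junction keeps its flip probability, and the lumen volume, solved from
$[v(N)+N]^{1/3} - v(N)^{1/3} = 400^{1/3} - 100^{1/3}$ anchored at
$v(300) = 100$, so the spherical-shape threshold in $(\alpha,\beta)$ is
size-independent. In growing shells the same relation is applied with $N$
replaced by the total tissue target volume, every step.

## Morphometrics

* **Reduced volume** $v = 6\sqrt{\pi}\,V/A^{3/2}$ of the midplane surface
  (vertices halfway between apical and basal partners); 1 for a sphere.
* **Cell height and curvature**: $h$ is the distance between the apical and
  basal face centroids; the cell's mean curvature is that of a truncated
  cone with the same apical area, basal area and height,
  $c = (2/h)(\sqrt{a_\mathrm{b}}-\sqrt{a_\mathrm{a}})/
  (\sqrt{a_\mathrm{b}}+\sqrt{a_\mathrm{a}})$.
* **Thickness modulation** $\delta = p\,\Delta h/\bar h$ with $\Delta h$
  half the full height range (a quantile-based robust variant is available),
  $\bar h$ the mean height, and $p$ the sign of the Pearson correlation
  between $c$ and $h$.
* **$h(c)$ fits**: a least-squares line per shell; across shells the
  intercept tracks the flat-epithelium height and the slope
  $\lambda_1 + (\alpha-\beta)\lambda_2$ with $\lambda_1 = -0.059$,
  $\lambda_2 = 0.45$, which the `collapse_transform()` uses to overlay all
  shells on one master line.
* **Topological pair correlations** $g_\gamma(d)$: the mean number of
  $\gamma$-gons at graph distance $d$ from a $\gamma$-gon (per shell,
  unweighted across an ensemble; shells without a $\gamma$-gon are omitted
  and counted).
* **Anisometry** $\kappa = (g_1-g_2)/(g_1+g_2)$ of the two largest
  gyration-tensor eigenvalues of a face's vertices.

The **morphology classifier** operationalises what is a by-eye call at
full scale: nonphysical if self-overlapping; spherical above a reduced-volume
threshold; stomatocyte when a sizable fraction of cells curves inward
($c<0$); otherwise budded or branched by the number of connected groups of
strongly outward-curved cells. Its thresholds (`morphology_config()`) are
calibration constants fixed once against the four reference parameter sets
- $(\alpha,\beta)$ = (1.2, 1.2) spherical, (0.5, 1.1) stomatocyte,
(1.1, 0.5) budded, (0.7, 0.5) branched under activity - and the boundaries
between classes are soft by nature (near-boundary shapes report `hybrid`).

Because the model has no steric repulsion, strongly deformed shells at the
small sizes used here routinely bring walls into grazing contact. The
self-overlap screen therefore shrinks every surface triangle by a factor
0.95 toward its centroid before the exact intersection test: contact is
tolerated, a wall passed through another is still flagged. Only final
snapshots are screened; transient overlaps during dynamics are expected.

## Continuum theory

Coarse-graining the cell energy over truncated-pyramid cells gives the
energy per unit midplane area

$$\frac{dw}{da} = (\alpha+\beta)
 + 2\Bigl[1-\tfrac{(\alpha-\beta)^2}{4}\Bigr]\sqrt{h^3}
 + \frac{\sqrt h}{8}\bigl[c_1+c_2-2\sqrt h(\alpha-\beta)\bigr]^2
 + \Bigl(\tfrac{\alpha+\beta}{4}+\tfrac{\sqrt{h^3}}{12}
        -\tfrac{1}{4\sqrt{h^3}}\Bigr)h^2c_1c_2,$$

i.e. a surface tension, a local bending term with modulus $\sqrt h/8$ and
spontaneous curvature $c_0 = 2\sqrt h(\alpha-\beta)$, and a Gaussian term -
all thickness-dependent. For a flat sheet of identical hexagonal cells the
force balance $\partial w/\partial h = 0$ with $ha = 1$ gives
$h_0 = (2^{1/3}/3^{1/6})(\alpha+\beta)^{2/3}$, $a_0 = 1/h_0$, and estimating
the shell midplane area as $N_\mathrm{c} a_0$ yields the linear
reduced-volume prediction
$v = 2^{3/2} 3^{3/4} \sqrt{\pi}\, v_\mathrm{midplane}
(\alpha+\beta)/N_\mathrm{c}^{3/2}$.

An important caveat, used when interpreting the package's own acceptance
checks: the flat-sheet height $h_0$ is attained only where the shell is free
to choose its area - that is, in *non-spherical* shells below the spherical
threshold, and right at the threshold. Above it, a closed spherical shell
with both cell volumes and lumen pinned has its thickness fixed by geometry,
$h \approx [3(v+N)/4\pi]^{1/3} - [3v/4\pi]^{1/3}$, independent of tension,
and the measured mean height plateaus there no matter how large
$\alpha+\beta$ grows. The height check against $h_0$ therefore passes near
the threshold tension and fails by construction deep in the spherical
domain; the corresponding acceptance test reports exactly that.

## Numerical choices and scales

* **Geometry.** Every face - the polygonal apical/basal faces and the
  generally non-planar lateral quads - is triangulated by a fan from its
  vertex centroid; volumes use the divergence theorem over the same fans.
  This makes areas and volumes smooth in the vertex positions, so the force
  is an exact analytic gradient (cross-checked against central finite
  differences at $10^{-6}$ relative tolerance in the tests).
* **Time step.** $\delta t = 10^{-4}$ is the contract default. The explicit
  Euler scheme remains stable at $2$-$5\times10^{-4}$ for passive
  relaxations at $K = 100$; tests and the acceptance script use such larger
  steps for relaxation-only runs and keep $\delta t$ small where T1
  mechanics matter. Energy monotonicity along passive trajectories is
  asserted at every logged interval.
* **Problem sizes.** Full-scale runs ($N_\mathrm{c} = 300$,
  $t_\mathrm{max} = 1000$, ensembles of hundreds) are cluster-scale. The
  test suite and acceptance script work with 32-64-cell shells for
  property checks and 100-cell shells with a compressed activity ramp
  ($t_\mathrm{max} = 40$) for the morphology checks; these sizes were
  chosen once as the smallest at which the four reference morphologies are
  distinguishable. At 64 cells and below, the rescaled lumen is so small
  that deep invaginations contact the opposite wall - the reason the
  morphology checks run at 100 cells.
* **Determinism.** All randomness (T1 draws, OU noise, growth entries,
  division side choices) flows through R's RNG in a fixed per-step order,
  so a run is bit-reproducible from (seed, config) and independent of how
  the compiled inner loop is chunked; snapshots carry positions at 17
  significant digits plus the RNG state, open rosette dwells and refractory
  junctions, making save/resume bit-exact.

## What the generator does and does not emulate

Synthetic shells start from near-spherical Thomson-dual packings with
identical cells - the model's own idealisation. They reproduce the
area-volume incompatibility, the activity-dependent fluidisation, and the
defect-curvature coupling that drive the four morphologies, and they are the
conditions under which all quantitative checks here are performed. They do
not include differentiated cell types, apoptosis or extrusion, planar cell
polarity, substrate mechanics, or curved-face geometry; passing tests
therefore say nothing about tissues where those dominate. Passive (no-T1)
budding at small $N_\mathrm{c}$ is kinetically trapped on accessible time
scales - the spherical state is metastable - so budded reference shapes are
produced with the active protocol, as at full scale.
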