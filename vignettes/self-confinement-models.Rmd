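---
title: "Reaction–diffusion models of self-confined gene expression in the root stem-cell niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-diffusion models of self-confined gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In the *Arabidopsis thaliana* primary root, the stem-cell niche (SCN) is
organized around the quiescent centre (QC). Two transcription factors are
co-expressed there: WOX5, produced in the QC and able to move to adjacent
cells, and BRAVO, expressed in the QC and the vascular initials (VI).
In a *bravo* loss-of-function background the activity of the *BRAVO*
promoter does not disappear — it *expands* shootward into the vasculature.
BRAVO therefore confines its own expression domain, and the confinement
requires WOX5.

This package implements and analyses a family of one- and two-dimensional
reaction–diffusion models of that self-confinement. All of them share one
idea: *attenuation of a mobile activator*. BRAVO is immobile; its
transcription is driven by a diffusible signal that originates from WOX5;
and BRAVO weakens that signal, either by

* **immobilization by sequestration** — BRAVO binds WOX5 into an immobile,
  transcriptionally inactive complex that is degraded, removing free WOX5
  from the mobile pool; or
* **repression** — BRAVO represses the production of a diffusible
  intermediary Z, which is activated by WOX5 and in turn activates BRAVO.

The **mixed** model carries both arms at once.

# Model variants

Concentrations are functions of position and time; every species degrades
linearly; binding follows mass action. In one dimension the QC occupies
$-L_{QC}/2 \le x \le L_{QC}/2$ (both ends inclusive) and the VI region,
of the same length, ends at $x_{VI} = 3L_{QC}/2$.

**Sequestration** (`variant = "sequestration"`):

$$\partial_t B = P_B(W, x) - d_B B - \lambda B W$$
$$\partial_t W = P_W(W, x) - d_W W - \lambda B W + D_W \partial_x^2 W$$

$P_B$ is either linear, $\alpha_L W\,\Theta(x + L_{QC}/2)$, or saturating,
$\alpha W^n/(k_B^n + W^n)\,\Theta(x + L_{QC}/2)$; the Heaviside factor
$\Theta$ restricts BRAVO activation to the QC-to-vasculature side, mimicking
the asymmetry of *BRAVO* expression (nothing on the columella side).
$P_W = \gamma$ inside the QC and $0$ outside; with WOX5 negative feedback it
becomes $\gamma/(1 + (W/k_W)^h)$, so that production is $\gamma/2$ at
$W = k_W$ for any $h$. The bilinear loss $\lambda BW$ is the sequestration
arm: $\lambda$ lumps the association, dissociation and complex-degradation
rates of the explicit complex description (below).

**Sequestration with intermediary Z** (`"sequestration_z"`) inserts a
diffusible species Z between WOX5 and BRAVO: $P_B$ takes Z as its argument
and Z obeys
$\partial_t Z = P_Z(W) - d_Z Z + D_Z \partial_x^2 Z$ with
$P_Z = \beta_L W$ (linear) or $\beta W^n/(k_Z^n + W^n)$.

**Repression** (`"repression"`) drops the binding ($\lambda$ unused) and
multiplies $P_Z$ by $1/(1 + cB)$. The choice of the repression factor is a
design decision: the multiplicative form makes $c = 0$ remove the
repression *exactly*, which the reduced-variant comparisons rely on; the
exponent is fixed at 1.

**Mixed** (`"mixed"`) has both the $\lambda BW$ terms and the
$1/(1 + cB)$ factor.

Two more variants support robustness analyses:

* `"sequestration_S"` adds a competing sequestrator S (standing in for
  other BRAVO/WOX5 binding partners such as TPL or BES1), produced
  uniformly at rate $\alpha_S$, diffusing with $D_S$ under periodic
  boundary conditions, degraded at $d_S$ and binding WOX5 with
  $\lambda_S$; the S–W complex is immobile and inactive. Because the
  original description of this variant is only sketched, its equations are
  an explicit assumption of this package: S binds only WOX5 (not BRAVO),
  and S production is spatially uniform.
* `"full_complex"` models the BRAVO–WOX5 complex C explicitly:
  $\partial_t C = k_{on} BW - (k_{off} + d_C) C$ with matching exchange
  terms on B and W. Its stationary solutions coincide with the minimal
  sequestration model at
  $\lambda_{eff} = k_{on} d_C/(k_{off} + d_C)$: confinement requires the
  complex to be irreversible or degraded; a reversible, non-degrading
  complex ($d_C = 0$) gives $\lambda_{eff} = 0$ and no confinement. The
  package uses this variant as an internal consistency check, not as a
  primary model.

**Genotype transform.** The *bravo* mutant is simulated with the same
equations and parameters but $B(x, t) = 0$ for all $x$ and $t$ (no
dynamical equation for B). The *BRAVO promoter* is still active: its
stationary activity $pB$ is computed from the mutant's stationary activator
profile. Promoter activities are always the production functions evaluated
on the stationary profiles: $pB = P_B(\cdot_s, x)$,
$pW = P_W(W_s, x)$, $pZ = P_Z(W_s, B_s)$.

# Two solver routes

The stationary profiles are computed by two independent routes, and their
agreement is asserted by the test suite — this mirrors the validation used
when the models were first studied.

**Boundary-value route** (`solve_stationary_bvp()`). The reaction equations
of the non-diffusible species are set to zero and substituted: for the
sequestration family, $B = P_B/(d_B + \lambda W)$; a non-diffusible Z
(used in the cell-autonomous reduction) is eliminated by a damped fixed
point of $Z = P_Z(W, B(Z))/d_Z$, which is a contraction because $P_Z$
decreases with B and B grows with Z; an immobile W (repression variant)
reduces to its pointwise production–degradation balance. The remaining
second-order system, with zero Dirichlet boundaries, is discretized with
central differences on the user grid (default $\delta x = 0.05$ on
$[-600, 600]$) and solved by a damped Newton iteration: the Jacobian is
the constant sparse diffusion block plus a node-local reaction block
obtained by one finite-difference sweep per species pair; a line search
with Levenberg fallback guards the iteration. Convergence is declared at a
stationary-residual max-norm below $10^{-8}$, which cleanly separates
converged solutions from slow transients at these parameter scales.
Newton iterates may transiently dip below zero; reaction terms are
evaluated on clamped values, which leaves the solution (positive in the
interior) untouched.

**Forward-Euler route** (`integrate_to_steady()`). The full
time-dependent equations are integrated from all-zero initial conditions
with zero Dirichlet boundaries and the three-point Laplacian, by default
with $\delta x = 1$ on $[-400, 400]$, $dt = 0.01$ and $t_{final} = 1000$.
The explicit stability bound $dt\,D/\delta x^2 \le 1/2$ is checked for
every diffusive species before stepping. The returned state carries the
final rhs residual and the relative field change over the last 1% of
steps. The inner loop is compiled (Rcpp); the sequestrator S uses a
periodic wrap in the same kernel.

The two routes use deliberately different grids (fine vs coarse, as in the
original analyses); cross-comparisons interpolate the fine solution onto
the coarse grid and normalize the maximum deviation by the profile
maximum. One numerical subtlety: a source indicator sampled at grid nodes
with inclusive boundaries carries an $O(\delta x)$ mass error at the two
QC edges, so the closed-form comparison (below) uses $\delta x = 0.01$,
where that edge effect is far below the 0.1% tolerance.

# Observables and parameter scans

Four observables compare a wild-type/mutant pair:

* $\Delta x$: the wild-type reference level is
  $pB^\ast = pB^{wt}(x_{VI})$; $x^{bravo}$ is the largest position where
  the mutant $pB$ crosses $pB^\ast$ (linear interpolation between nodes on
  the decaying tail; the rightmost crossing is used because the quantity
  measures *expansion*, with a warning if the tail is non-monotone);
  $\Delta x = x^{bravo} - x_{VI}$ and $\xi = \Delta x / L_{QC}$. A mutant
  profile that never reaches $pB^\ast$ yields the sentinel
  $-(x_{VI} - x_{min})$ with a warning.
* $R_B = pB^{bravo}(0)/pB^{wt}(0)$, the fold-increase at the QC centre.
  The centre value is taken at the point $x = 0$ (not a QC average): the
  profiles are flat at the QC centre, so the two readings differ
  negligibly while the point value is unambiguous.
* $R_{BW} = pB^{wt}(x_{VI})/pW^{wt}(0)$, *BRAVO* vs *WOX5* expression in
  the wild type.
* $R_W = pW^{bravo}(0)/pW^{wt}(0)$, reported only when the model couples
  BRAVO to the WOX5 promoter (binding *and* WOX5 self-repression), since
  otherwise $pW$ is state-independent and the ratio is identically 1.

Compatibility with the reported root phenotypes means (inclusive ranges):
$\xi \in [0.5, 5]$, $R_B \in [1, 2]$, $R_{BW} \in [0.05, 0.5]$ and, when
applicable, $R_W \in [0.5, 0.9]$. `scan_plane()` evaluates a
$15 \times 15$ log-spaced lattice per parameter plane via the Euler route
(the route the published heatmaps used), records all observables plus the
AND-verdict per cell, and turns per-cell solver failures into
`compatible = FALSE` rows with a reason rather than aborting. Zero-valued
controls ($\lambda = 0$, $D = 0$) cannot sit on a log grid and are run as
separate single-point evaluations.

# Synthetic root layouts and segmentation

The 2D simulator consumes a labeled pixel grid. Because the original
segmented confocal midplane is not redistributable, the package generates
*synthetic* layouts (`layout_template()`, `generate_layout()`): a
rectangular root of tissue files (lateral root cap, epidermis, cortex,
endodermis, pericycle and three vascular files, mirrored) crossed by cell
rows (three columella tiers, columella stem cells, the QC row, the VI row,
then body rows), every cell separated by 2-pixel walls, one pixel
$\approx 0.5\,\mu m$. The wild-type preset is a $228 \times 448$ lattice;
the mutant preset $231 \times 448$; a $100 \times 200$ `mini` preset keeps
simulations fast. The eleven cell types (QC, VI, V, CEI, PER, CX, END,
EPI, CSC, CC, LRC) are assigned from the file/row recipe; the QC sits in
the vascular files of the QC row, flanked rootward by CSC and CC tiers and
shootward by the VI row.

The generator also renders a stain image (bright walls, dark interiors,
clipped Gaussian noise), on which `segment_image()` runs the same pipeline
a real image would get: global Otsu threshold, morphological
skeletonization (Zhang–Suen) re-dilated to the fixed 2-pixel wall width,
and 4-connected labeling of the non-wall regions — 4-connectivity prevents
diagonal leaks through the 2-pixel walls. Components touching the image
border are merged into the single outside label; the root outline wall
belongs to the wall label; cells below 4 px are folded into the wall with
a warning.

What the synthetic layouts do **not** emulate: irregular cell outlines,
intensity gradients and stain bleed-through of real propidium-iodide
images, or the anatomically curved columella/LRC geometry. A perfect
round-trip on synthetic stains therefore validates the pipeline's
mechanics (thresholding, thinning, labeling, typing), not its robustness
to real microscopy artifacts.

# The 2D pixel-grid engine

`ftcs_run()` integrates the mixed model (and its $\lambda = 0$, $c = 0$,
cell-autonomous-Z reductions) with a forward-time central-space scheme,
default $\Delta t = 0.1$ up to $t = 3000$, from zero initial conditions.
Space is heterogeneous: each species has a cytoplasmic diffusivity on cell
pixels, a smaller one on wall pixels (walls gate cell-to-cell transport),
and zero outside the root. BRAVO and (implicitly) the complex cannot cross
walls at all. The diffusion operator is conservative (flux form); the face
diffusivity between two pixels is the arithmetic mean of the two pixel
values, and a face with zero diffusivity on either side carries no flux —
this implements reflecting boundaries at the root outline automatically
and conserves mass to machine precision. The arithmetic mean was chosen
(the harmonic mean was considered) because with hard zero/nonzero
boundaries the two coincide where it matters, and the arithmetic mean
keeps the "smaller wall D gates transport" reading of a 2-px wall.

Reactions (production, degradation, binding) act on cell pixels only;
inside walls only diffusion happens. WOX5 is produced only in QC cells;
WOX5(-driven Z) activates BRAVO only in QC, VI, vascular, cortex and
endodermis cells; a small designated set (the VI cells by default)
carries WOX5-independent basal BRAVO production. Three GFP reporters share
one diffusion coefficient and one degradation rate and inherit the
production term of their cognate species — so in the *bravo* mutant the
BRAVO protein field is held at zero while its reporter still evolves,
which is exactly why the mutant reporter is invariant under changes of
$\lambda$ and $c$ (used as a consistency check).

One geometric consequence worth stating: wall pixels carry no degradation,
so the 2-px wall ring around the QC equilibrates toward QC concentrations
and holds a geometry-determined share of the total WOX5 mass
(about 40% at the `mini` cell sizes). The "WOX5 stays in the niche"
localization check (`region_mass_fraction()`) therefore counts the
QC+VI+CSC cell pixels *plus the wall pixels adjacent to them* — the wall
ring belongs to the niche spatially. No parameter choice could satisfy a
cell-pixel-only reading of that check; this is a property of the
wall model, not of the rates.

# Default parameters

Grids, steps, the QC length ($L_{QC} = 15$ a.u.), the lattice sizes and
the compatibility ranges are fixed, printed quantities of the framework.
The kinetic defaults (all in arbitrary units) are package choices,
calibrated once so that every shipped variant lies inside the
compatibility ranges and the two solver routes agree to better than 1%:

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | WOX5 production in the QC (conc/time); sets the concentration scale |
| `d_B, d_W, d_Z` | 0.1, 0.05, 0.05 | degradation (1/time); lifetimes of 10–20 time units |
| `alpha_L` | 0.1 | linear BRAVO production per unit activator (1/time) |
| `alpha, k_B, n` | 0.5, 0.2, 2 | saturating BRAVO production (conc/time), half-point, cooperativity |
| `k_W, h` | 2, 1 | WOX5 self-repression half-point and exponent (h is unstated in the source framework; 1 is the weakest choice and the $\gamma/2$ anchor holds for any h) |
| `beta, k_Z` | 1, 0.5 | Z production and half-point |
| `lambda` | 0.2 | sequestration strength (1/(conc·time)) |
| `c` | 1 | repression strength (1/conc) |
| `D_W` | 10 (4 with intermediary; 0 in the repression variant) | WOX5 diffusivity (length²/time): decay length $\sqrt{D_W/d_W} \approx 14$ a.u., about one QC length |
| `D_Z` | 4 | Z diffusivity |
| `alpha_0` | 0.01 | basal BRAVO production in the VI |

The 2D defaults (`default_params_2d()`, `params2d()`) differ where pixel
units demand it: diffusivities are bounded by the FTCS stability limit
($D \le 2.5$ px²/time at $\Delta t = 0.1$), WOX5 turnover is faster and
its wall mobility low (it barely leaves the niche), while Z is long-lived
and wall-mobile so that it can carry the activation signal outward; both
regulatory arms are strong ($\lambda = 1$, $c = 10$) so that the wild type
visibly confines the reporter while the mutant expands it by more than one
cell row.

# Problem sizes and runtimes

The default 1D runs use the printed grids (24,001 BVP nodes; 801 Euler
nodes, $10^5$ steps). Scans solve 450 stationary problems per plane; the
test suite and the acceptance script run them at $t_{final} = 300$, which
is 15 or more lifetimes of every species and leaves the verdicts
unchanged. 2D checks use the $100 \times 200$ `mini` layout at the full
$t = 3000$. One slow case needs more time: with a reversible,
non-degrading complex the free pools approach stationarity on the
complex-equilibration timescale, so that check integrates to
$t = 12000$.

# Known limitations

* The 1D geometry is a caricature: $\xi$ values are not expected to match
  measured root expansions quantitatively, only to fall in the stated
  compatibility window.
* No transcription/translation delays, no stochastic dynamics, no 3D
  geometry, no cell growth or division; plasmodesmata are abstracted into
  a wall diffusivity.
* The repression functional form ($1/(1+cB)$, exponent 1) and the
  sequestrator-S equations are package assumptions where the source
  framework is underspecified; both are flagged in the code.
* Parameter defaults are calibrated representatives of the compatible
  regions, not fitted values.
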