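---
title: "Lattice dose-response mapping of cloud shine and ground shine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice dose-response mapping of cloud shine and ground shine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shinemap)
```

## The problem

After an atmospheric release of radioactive material — a reactor accident,
a dirty-bomb event, or routine stack emissions from a reprocessing
facility — the external gamma-ray dose at ground level has two components:
*cloud shine* from the overhead plume and *ground shine* from activity
deposited on surfaces.  Emergency response needs a dose-rate map over a
km-scale domain within minutes, which rules out full Monte Carlo photon
transport for each new concentration snapshot.

`shinemap` takes the standard shortcut: all transport physics is
pre-computed once into a **lattice dose-response function** $R(l, m, n)$ —
the dose rate at a ground-level receptor (1 m above grade) per unit
activity (1 kBq) in a source cell at horizontal offset $(l, m)$ and
vertical layer $n$, with $n = 0$ an areal source on the ground and
$n \ge 1$ a volume source in the air.  A dose map is then a lattice
convolution with the gridded activity field $C$:

$$\dot D(x_i, y_j) \;=\; \sum_{l=-L}^{L}\sum_{m=-M}^{M}\sum_{n=0}^{N}
  R(l, m, n)\, C(x_i + l,\, y_j + m,\, n),$$

with two refinements: straight-line attenuation
$\exp(-\mu L_{S \to T})$ through obstacle voxels (buildings), and a
terrain-elevation index offset $h$ that substitutes $R(l, m, n - h)$ for
elevated target cells (cloud shine only).

## The response-function surrogate

The lattice is built from a point-kernel model rather than Monte Carlo
transport.  For each packaged gamma line (energy $E$, intensity $I$) the
contribution of a source element at distance $r$ is

$$\frac{1000\, I\, c(E)}{4\pi r^2}\, e^{-\mu_a r}\, B_w(\mu_a r),$$

where $\mu_a$ is the linear attenuation coefficient of air at $E$, $c(E)$
the fluence-to-dose conversion coefficient (ambient dose equivalent
H\*(10) or air kerma), and $B_w$ a Berger buildup factor
$1 + a\,\mu_a r\, e^{b \mu_a r}$ representing in-air scatter.

Two geometry effects matter:

* **Ground truncation of scatter.**  An infinite-medium buildup factor
  overestimates the scattered component of near-ground paths, because a
  large part of the scattering volume would be below grade.  The package
  scales the scattered part $(B - 1)$ by the fraction of a sphere of one
  mean free path, centred at the ray midpoint height $\bar z$, that lies
  above the ground plane: $w = \tfrac12 + \tfrac34 t - \tfrac14 t^3$ with
  $t = \min(\bar z \mu_a, 1)$.  This single correction reproduces the
  characteristic crossover of cloud-response curves: close to the
  receptor a 10-m source layer dominates a 100-m layer, but beyond
  roughly 250 m the low layer falls below the high one because its
  near-ground scatter is suppressed.  The packaged surrogate puts the
  crossover at 236 m (recomputed in the test suite and acceptance
  script).
* **Sub-surface chords.**  If a ray endpoint lies below grade the segment
  below $z = 0$ is additionally attenuated with the soil coefficient.
  With the standard receptor height of 1 m this path is rarely exercised,
  but it keeps the kernel meaningful for arbitrary endpoint geometry.

Near-field source cells (centre distance under 10 m) are integrated with
6-point Gauss–Legendre quadrature per dimension over the source patch or
voxel; more distant cells use a midpoint evaluation.  Six points (rather
than an odd count) are used so no quadrature node coincides with the cell
centre — the receptor can sit *inside* the lowest cloud voxel, where the
inverse-square integrand is singular but integrable.

The native lattice covers a 1001 m × 1001 m horizontal domain at 1 m
resolution, with cloud layers at 17 altitudes (1–1000 m).  Intermediate
altitudes are interpolated log-log; coarser resolutions are produced by
centred block means, truncating division remainders (for even ratios the
centre block is biased half a cell low, a documented convention).
Archives are stored as little-endian IEEE-754 doubles in a stream file
with a fixed header.

Because the resized value is a block *mean*, it is the dose per unit
**total activity** in the coarse cell; the engine therefore multiplies
responses by per-cell activity in kBq (density × cell area or volume).
At native 1-m resolution this is numerically identical to using densities
directly.

The absolute magnitude of the lattice is validated against closed-form
limits (inverse-square vacuum kernel, brute-force patch quadrature) and
qualitative transport behaviour, not against published tabulations — no
reference lattice values are available at this fidelity level.

## Sources

Two source models feed the engine:

* A **steady-state Gaussian plume** with total ground reflection,
  $C = \frac{Q}{2\pi \sigma_y \sigma_z U} e^{-y^2/2\sigma_y^2}
  [e^{-(z-H)^2/2\sigma_z^2} + e^{-(z+H)^2/2\sigma_z^2}]$.  The
  Pasquill–Gifford dispersion curves are graphical, so the package adopts
  the Briggs open-country closed forms per stability class (e.g. class D:
  $\sigma_y = 0.08x(1+10^{-4}x)^{-1/2}$,
  $\sigma_z = 0.06x(1+1.5\times10^{-3}x)^{-1/2}$).  Cell means use
  3-point Gauss–Legendre quadrature per dimension; upwind cells are zero
  by convention and flagged, since target areas extend upwind of the
  stack.  The canonical cases use Q = 1 Bq/s, U = 1 m/s, H = 150 m; no
  stability class is fixed by the case definitions, so the generator
  defaults to neutral (D) with an override.  Because of that open choice,
  absolute dose maps of the plume cases are not used as quantitative
  benchmarks; mass-flux conservation (better than 0.1 %) is.
* A **building-array surrogate** for an unsteady release: a 240 m ×
  240 m × 150 m domain, 5 × 5 cubic buildings of 24 m side (modelled as
  90 % air / 10 % concrete, bulk density 0.24 g/cm³, attenuation
  coefficient 1.85 m⁻¹), 347.25 Bq of ¹³⁷Cs released at (−36, 0, 0) and
  advected downwind as a seeded Gaussian puff with crosswind meander.
  Dry deposition is accumulated at 0.1 cm/s on open ground and 0.05 cm/s
  on building walls and roofs; airborne plus deposited activity equals
  347.25 Bq at every snapshot by bookkeeping construction.  Wall and
  roof deposition (kBq/m²) is converted into the adjacent air cell
  (kBq/m³) conserving activity exactly; roofs convert upward.  The puff
  is a shape generator, not a turbulence model: channeling, recirculation
  and building-wake structure of a real large-eddy simulation are absent,
  so tests against these fixtures validate the *dose engine*, not
  dispersion fidelity.

## Numerical and design choices

* **Units.** Concentrations kBq/m³, deposition kBq/m², dose rates mSv/h
  (H\*(10)) or mGy/h (air kerma); conversion coefficients pSv·cm².
* **Interpolation.** All energy-indexed tables (mass attenuation, Berger
  coefficients, conversion coefficients) are interpolated linearly in
  log-log space.  Mixtures combine mass-attenuation by mass-fraction
  weighting of volume-fraction × density.
* **Ray geometry.** Sources at cell centres (ground sources at
  $z = 0^+$), targets at 1 m above local grade at the cell centre.  Rays
  are traced with an incremental voxel traversal that is exact for
  axis-aligned segments and handles non-uniform vertical layering.
  Streaming and scatter around obstacles are not modelled; behind
  buildings this over-shields (a known factor-of-several bias of the
  straight-line method), and far from sources the infinite-medium
  scatter assumption slightly over-estimates.
* **Determinism.** The per-cell summation order is fixed (layer, then m,
  then l, ascending), so the assembled map is bit-identical for any
  worker count.  Tiles are contiguous row-major runs differing by at
  most one cell in size, dispatched to a PSOCK worker pool with dynamic
  FIFO scheduling and an exactly-once completion ledger.
* **Skip rules.** Obstacle-occupied target cells are skipped (NA with a
  mask flag); zero-activity source cells are skipped with no effect on
  values.
* **Elevation.** Offsets are integer vertical cells from the lowest
  terrain level, rounded half-away-from-zero.  Ground shine is not
  evaluated at elevated cells (the areal lattice has no vertical offset
  dimension), and elevated soil does not shield — both documented
  limitations of the index-shift method.  When obstacles and elevation
  are both present the chord attenuation composes with the shifted term;
  the two features are rarely combined and the composition is the natural
  extension.
* **Problem-size accounting.** The index $N_T \times N_R \times N_{Sz}$
  counts target cells, resized-lattice cells and source-carrying vertical
  layers (ground counts as one).  For the full deposition job in the
  building array the package reproduces the canonical count
  $240^2 \times 1001^2 \times 25 = 1.44 \times 10^{12}$ under the
  convention that the 24 one-metre wall layers plus the ground layer
  carry source; the roof-converted layer above 24 m is excluded from that
  counting convention (it is included in actual dose computations).

## Problem sizes used in the checks

The test suite and acceptance script run reduced problem sizes chosen to
exercise every code path at full numerical fidelity: oracle comparisons
on 21 × 21 × 5 scenes against naive re-implementations (agreement at
machine precision), the crossover check on the full 1001 × 1001 native
lattice for two altitude layers, and the parallel-determinism check on
the building array at 4-m horizontal resolution with worker counts 1, 2,
4 and 8.  The 4-m reduction (rather than 2 m) keeps the five full map
evaluations desk-scale; resolution 1 m and 2 m are available through the
generator argument and change nothing structurally.  Published
speed-up/efficiency figures for 96-way cluster runs are treated as
arithmetic inputs ($S = T_{serial}/T_{parallel}$,
$\varepsilon = S/N$), not as benchmarks to reproduce: wall-clock
performance is hardware-specific and out of scope.

## Known limitations

* The point-kernel surrogate is not Monte Carlo transport: percent-level
  agreement with reference transport codes is out of reach by design, and
  published percentage comparisons against such codes are not reproduced.
* Obstacle attenuation uses one material and one energy-averaged
  coefficient per simulation; energy degradation in walls is ignored.
* No plume depletion feeds back from deposition into the Gaussian plume
  model (the building-array surrogate does deplete its puff).
* Single-snapshot fields; no time integration of committed dose.
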