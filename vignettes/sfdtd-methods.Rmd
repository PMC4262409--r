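---
title: "Methods: high-order symplectic FDTD and SAR dosimetry in a tissue phantom"
author: "sfdtd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-order symplectic FDTD and SAR dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdtd)
```

# The problem

Radio-frequency fields of MRI systems (1.5 T and 3 T scanners operate near
64 and 128 MHz) deposit power in conductive tissue. The deposited dose is
quantified by the specific absorption rate,

$$\mathrm{SAR} = \frac{\sigma\,(|E_x|^2_{\mathrm{peak}} + |E_y|^2_{\mathrm{peak}})}{2\rho}
\quad [\mathrm{W/kg}],$$

with $\sigma$ the tissue conductivity (S/m), $\rho$ its mass density
(kg/m³), and the peaks taken over a steady-state cycle of the harmonic
field. This package simulates a simple concentric mother/fetus phantom
(uterus, placenta, fetus discs) exposed to a plane wave at these
frequencies, with an optional Drude-plasma protective arc, and asks two
questions: how stable and accurate is the field solver over long runs, and
how much does the protective layer reduce the peak SAR?

Long-run fidelity is the reason for the solver design. Maxwell's equations
form an infinite-dimensional Hamiltonian system; a time integrator that
respects that structure (a *symplectic* integrator) exhibits no secular
energy drift, whereas a non-structure-preserving discretisation slowly
corrupts amplitudes over thousands of steps. The solver therefore combines:

* a **symmetric split-operator (Yoshida) composition** in time — the
  electric and magnetic sub-updates are alternated with stage weights
  $c_l, d_l$ that sum to one and satisfy the palindromic symmetry relations
  $c_l = c_{m+1-l}$, $d_l = d_{m-l}$, $d_m = 0$; and
* **fourth-order staggered differences** in space on the Yee lattice,
  $f'(x_{i+1/2}) \approx [a_1 (f_{i+1} - f_i) + a_2 (f_{i+2} - f_{i-1})]/\Delta$
  with $a_1 = 9/8$, $a_2 = -1/24$ (the unique fourth-order two-pair
  staggered stencil from Taylor expansion; exact on cubics).

A classic second-order Yee leapfrog (`scheme = "fdtd22"`) is kept as the
comparison baseline.

# Time integration

## Stage coefficients

The default composition is the fourth-order Yoshida triple jump: with
$w_1 = 1/(2 - 2^{1/3})$ and $w_0 = 1 - 2 w_1$, concatenating second-order
split half-steps and merging adjacent same-operator factors gives

```{r}
yoshida_coefficients()
```

Note the negative middle weights: the composition takes a *backward*
sub-step. That is intrinsic to symmetric compositions of order greater than
two and has two practical consequences handled below (loss splitting and
the absorbing boundary). The published five-stage fourth-order families
derived via the Baker–Campbell–Hausdorff expansion are not hard-coded —
their printed values vary between sources — but any user-supplied set is
accepted and validated by `load_stage_coefficients()`, and its order can be
*measured* with `empirical_order()` rather than trusted.

## Stability

For a single spatial Fourier mode the staged update collapses to a product
of $2\times2$ shears; the scheme is stable while the one-step trace stays in
$[-2, 2]$. `stage_stability_limit()` scans this product: the Strang/leapfrog
interval is the textbook $x \le 2$, the Yoshida composition's is reduced to
$x \approx 1.57$. Combining with the stencil symbol maximum ($7/3$ for the
fourth-order pair, $2$ for the two-point stencil) gives the Courant limit

$$ S_{\max} = \frac{x_{\max}}{g_{\max}\sqrt{d}} $$

in $d$ dimensions (`cfl_limit()`). All studies run at Courant number 0.5
(defined as $c_0 \Delta t \sqrt{d} / \Delta$), comfortably inside the limit
for both schemes so that the long-run comparison uses one common time step.

## Measuring the order

`empirical_order()` runs a lossless 1-D PEC-cavity standing mode at a fixed
fine grid and halved time steps and fits the L2-error slope. Two
methodological details matter:

* the reference is the **semi-discrete** solution — the mode oscillating at
  the stencil-modified frequency $\tilde\omega = c_0 \tilde k$ — so the
  measured error is purely temporal;
* the error is evaluated at 0.37 of a period, **not** at a full period: at a
  period boundary the field sits at a cosine extremum where phase error
  enters only quadratically, which inflates the fitted order (a leapfrog
  control then appears fourth-order accurate).

With these choices the fitted orders are 2.00 for the Strang control and
4.00 for the Yoshida set, and the spatial refinement study in
`convergence_report()` (fixed Courant number, grid halving, true closed-form
reference) fits ≈ 3.98.

# Media

## Lossy dispersive tissue

Tissue enters through its relative permittivity and conductivity at the
operating frequency (the built-in `tissue_table()` holds the uterus,
placenta, and fetus values at 64 and 128 MHz together with mass densities).
The solver marches the normalized flux density $D$ and recovers $E$ through
the conductivity running-sum form of the frequency-domain constitutive law
$D(\omega) = (\varepsilon_r + \sigma/(i\omega\varepsilon_0)) E(\omega)$:

$$ E^n = \frac{D^n - \frac{\sigma \Delta t}{\varepsilon_0}\sum_{k<n} E^k}
             {\varepsilon_r + \frac{\sigma \Delta t}{\varepsilon_0}},
\qquad \text{then } \textstyle\sum \mathrel{+}= E^n. $$

For $\sigma = 0$ this is exactly the instantaneous law $E = D/\varepsilon_r$
at every stage, so the lossless fourth-order accuracy is untouched.

**Loss splitting across stages.** Applying the running-sum update per
symplectic sub-step (with $\sigma c_l \Delta t$) looks natural but is
*unstable*: during the backward stage the loss term becomes gain, and the
composition of an electric-field-only gain with the stage rotations has
spectral radius above one — in a test cavity with $\varepsilon_r = 4$,
$\sigma = 0.02$ S/m the energy grew by a factor $10^{36}$ over 1500 steps.
The package therefore advances the running sum (and the plasma current)
**once per full step** at the final electric stage, using the frozen sum in
the earlier stages. For a one-stage scheme this reduces exactly to the
standard per-step update; the splitting is first-order in the loss operator,
which is the accuracy of the running-sum quadrature anyway. A closed lossy
PEC cavity then dissipates monotonically after source switch-off, and a
driven cell absorbs non-negative cycle-averaged power (passivity).

## The Drude plasma layer

The protective layer is a collisional plasma handled by an auxiliary
current: $\dot J + \nu J = \varepsilon_0 \omega_p^2 E$, advanced with the
exponential (exact-in-$J$) one-step rule and fed back as a subtraction on
the flux density. Its analytic counterpart is
$\varepsilon(\omega) = 1 - \omega_p^2/(\omega(\omega - i\nu))$
(`drude_permittivity()`), used as the oracle in a 1-D slab-transmission
check against the transfer-matrix solution (`slab_transmission()`), which
agrees to well under 1%.

**Parameter conventions.** Quoted plasma parameters "plasma frequency
3 GHz, collision frequency 10 GHz" are read the way the plasma-shielding
literature quotes them: the plasma frequency is cyclic
($\omega_p = 2\pi \cdot 3\times10^9$ rad/s) while the collision frequency is
the Drude collision *rate* $\nu = 1/\tau = 10^{10}\,\mathrm{s^{-1}}$,
entering the model without a $2\pi$. This choice is not cosmetic: the
layer's low-frequency effective conductivity is
$\sigma_{\mathrm{eff}} = \varepsilon_0\omega_p^2/\nu \approx 0.31$ S/m under
this reading versus $0.05$ S/m with an extra $2\pi$ on $\nu$, and only the
rate reading reproduces the reported shielding magnitudes (see the results
note below). At 64 MHz the layer is far below its plasma frequency:
$\varepsilon \approx 0.91 - 88i$, i.e. an ohmic shield rather than a cut-off
reflector.

# The solver

Fields are stored in "E-units": electric fields in V/m and magnetic fields
as $Z_0 H$, so a vacuum plane wave has equal numeric amplitudes and both
curl updates carry a factor $c_0$. User-facing quantities (V/m, W/kg) need
no conversion.

## Boundaries

* **PEC** walls pin the tangential electric field to zero. In 1-D the wide
  stencil is closed with image-theory ghost values (E odd, H even across
  the wall), which is exact for the reflection and keeps the scheme
  uniformly fourth-order — a one-sided low-order closure would drag the
  measurable global order toward three.
* **Mur** first-order absorbing boundaries terminate open 2-D domains. The
  update is applied after *every electric stage* with the sub-step-scaled
  coefficient $(c_0 c_l \Delta t - \Delta)/(c_0 c_l \Delta t + \Delta)$:
  applied once per full step it reflects ~11% off the stale boundary value
  under the staged scheme, per stage ~0.3%. Near the outer edges (no image
  symmetry) the stencil falls back to second order in the two outermost
  layers.

## Sources

* `gaussian_source_spec()` — a hard (Dirichlet) Gaussian overwrite at one
  node, active for `t0 + active_factor * tau`; afterwards the node is
  released so returning reflections pass through. The default release
  residual is $e^{-12.5} \approx 4\times10^{-6}$ of the amplitude.
* `plane_wave_spec()` — a monochromatic plane wave travelling $+x$,
  injected through a total-field/scattered-field (TF/SF) window that
  encloses the phantom. The incident field is analytic; every wide-stencil
  tap that crosses the window boundary is compensated at the
  stage-accumulated electric/magnetic time. The amplitude ramps with a
  raised cosine over one period. Measured steady amplitude error inside the
  window is < 0.1% and leakage outside < 0.2% of the amplitude.
* `sine_soft_source_spec()` — an additive drive for calibration-free
  transmission measurements (transparent to passing waves).

## Polarizations

Both 2-D polarizations are provided: TE ($E_x, E_y, H_z$; `run_te2d()`) and
TM ($E_z, H_x, H_y$; `run_tm2d()`). At the MRI frequencies the phantom is
deeply sub-wavelength ($\lambda \approx 4.7$ m versus a 0.42 m phantom), and
the two polarizations couple to the protective arc in fundamentally
different ways: a thin, weakly conducting shell is nearly invisible to
in-plane electric fields (TE), while out-of-plane fields drive axial
currents in the shell whose screening scales as
$Z_0 \sigma_{\mathrm{eff}} d \, k R / 2$ (TM). Measured at desk scale, the
60° arc changes the TE peak SAR by ~0.1% (and non-monotonically in angle),
versus a monotone, passive 2–14% in TM. Field snapshots of this shielding configuration are conventionally shown
for the out-of-plane component, and that is the component the shell
actually screens, so **TM is the production mode of `sar_study()`** (SAR $= \sigma |E_z|^2_{\mathrm{peak}}/2\rho$),
with TE available via `mode = "te"`. The frequency comparison behaves
oppositely: the quasistatic TE coupling grows as $\omega^2$ and yields the
roughly fourfold 128-vs-64 MHz peak-SAR ratio, while TM yields ~1.2×; the
qualitative ordering (more absorption at 128 MHz) holds in both.

# The phantom

`phantom_spec()` builds the month-9 geometry: nested discs of fetus
(100 mm), placenta (150 mm), and uterus (180 mm) radius — anatomically
plausible month-9 values, chosen once as the package defaults — on a 450 × 450
grid of 2 mm cells, with the plasma annulus from 190 to 210 mm (the stated
2 cm thickness) over a configurable angular arc facing the incident wave.
Classification is by cell centre (stair-cased, no partial-volume
averaging), and is evaluated *in grid units relative to the centre* so that
points landing exactly on a tissue circle or arc edge break ties
identically under mirror reflection — with naive metre-space arithmetic the
one-ulp asymmetry of `y - y_c` produced visibly asymmetric material rings.
Material properties are also sampled directly at each staggered field
location rather than averaged from cell centres.

The disc areas match $\pi r^2$ to better than 2% at full resolution, the
plasma cell count is strictly increasing in arc angle, and every map is
exactly mirror symmetric.

# Dosimetry protocol

The SAR study drives the phantom with a unit-amplitude plane wave, warms up
for one full source period (desk scale; two at full scale) after the
one-period smooth start, then tracks per-cell running peaks of the field
magnitudes over exactly one further period, and evaluates SAR per tissue
cell. An 800-iteration cold-start snapshot is sometimes quoted for this kind of
study; at any plausible cell size 800 steps span only a small fraction of a
64 MHz period, so peaks tracked that way carry start-up bias — the steady-state
protocol is the package default and the snapshot variant is kept only as a
`--legacy-800` CLI option for field-picture reproduction. This gap is
flagged deliberately.

"SARx" and "SARy" are read as the SAR profiles along the horizontal and
vertical lines through the phantom centre, with their maxima as the
reported scalars; component-wise SAR maps are also returned as a secondary
output. Peaks are interpolated from the staggered component locations to
cell centres (mean of adjacent values).

## Scales

* **desk**: 225 × 225 cells at 4 mm, one warm-up period (~3 300 steps per
  period at Courant 0.5). One angle case runs in seconds; the full angle
  sweep in under a minute.
* **full**: 450 × 450 cells at 2 mm, two warm-up periods; the same physics
  at roughly 20× the cost.

The desk scale is the default study size; all qualitative orderings
(frequency ordering, angle monotonicity, passivity, symmetry) are
scale-stable in our refinement checks.

# Results notes

* **Long-term cavity benchmark** (120 cells, unit hard Gaussian with
  $\tau = 12\Delta t$, $t_0 = 5\tau$, source 30 cells from the wall,
  Courant 0.5): at iteration 436 both schemes track the method-of-images
  solution to < 4% relative L2; at iteration 3146 the symplectic scheme's
  global peak is 0.9988 V/m with 1.5% L2 error while the second-order
  baseline's peak has fallen to 0.977 V/m with 31% L2 error. A unit hard
  source bounds the cavity peak by one (up to interference), so "the peak
  stays at 1 V/m" is satisfied to 0.1%; the separation between the schemes
  is the substantive claim.
* **Shielding study** (desk scale, TM, 64 MHz): the 60° layer reduces the
  x-axis profile peak by 13.6% and widening to 90° removes a further 4.9%
  — inside the 10–12% and 3.4–8.4% reference bands for this configuration —
  while 90°, 120° and 180° agree within 4%: the 90° arc is the economical
  angle. The **y-axis** profile peak, which sits at the
  top/bottom tissue surface outside the frontal arc's shadow, drops only
  2.6% (60°) and a further 2.1% (60°→90°): under the repo-default geometry
  the y-profile does not reach those bands, and a summary statistic defined
  as the smaller of the two profile reductions therefore stays below them.
  The reference geometry behind the bands (radii, layer placement) is not
  fully specified; this residual is documented rather than tuned away.

# What the generator does and does not emulate

The phantom is a stair-cased concentric-disc idealisation: it captures the
dielectric contrast, conduction loss, and geometric nesting of the tissues,
and it is exactly mirror-symmetric, which the property tests exploit. It
does **not** emulate voxelised anatomy, amniotic fluid or abdominal-wall
layers, tissue dispersion beyond the single-frequency conductivity model,
thermal effects, 1 g/10 g mass-averaged SAR, or the spatial non-uniformity
of a real birdcage coil (the incident field is a plane wave). Passing tests
demonstrate the solver's numerical properties and the relative,
qualitative dosimetry orderings — not absolute dosimetric accuracy for a
human subject.

# Numerical choices, degenerate inputs, limitations

* All arithmetic is double precision; runs are fully deterministic (no
  randomness anywhere), and repeat runs are bit-identical.
* Stage-coefficient validation tolerance is $10^{-12}$ on the sum and
  symmetry identities; first-order (non-symmetric) one-stage splits are
  accepted without the symmetry relations.
* Instability (non-finite fields) aborts a run with the offending step
  index.
* `staggered_diff4` falls back to the centred second-order difference at
  the two outermost midpoints where the wide stencil does not fit.
* The TF/SF window must keep at least four cells from the outer boundary
  so the corrected taps always use the wide stencil.
* First-order Mur absorbs normally incident waves to < 2%; obliquely
  incident scattered fields reflect more — the TF/SF window margin and the
  identical treatment across compared cases keep this bias common-mode.
* The 1-D solver's hard source is exactly consistent with the
  method-of-images oracle only while returning pulses do not cross the
  active source node; the default benchmark geometry respects this.
* 3-D domains, PML boundaries, graded meshes, and parallel decomposition
  are out of scope.
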