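# sfdtd — high-order symplectic FDTD simulation and SAR dosimetry in tissue phantoms

`sfdtd` is an R package for computational bioelectromagnetic dosimetry: it
solves Maxwell's equations in lossy dispersive biological tissue with an
explicit, high-order, symplectic finite-difference time-domain (SFDTD)
scheme and computes specific-absorption-rate (SAR) maps for a simple
concentric mother/fetus phantom exposed to MRI radio-frequency fields
(64 MHz / 1.5 T and 128 MHz / 3 T), with an optional Drude-plasma
protective layer.

It is written for physicists and engineers who want a small, fully
scriptable 1-D/2-D Maxwell laboratory whose numerical claims are testable:
every advertised property — order of accuracy, energy conservation,
absorbing-boundary quality, plasma-slab transmission, SAR symmetry — is
checked in the test suite against an independent oracle.

## The numerics in one paragraph

Maxwell's equations are a Hamiltonian system; marching them with a
*symplectic* split-operator composition prevents the secular amplitude
corruption that accumulates in the traditional Yee scheme over long runs.
The time stepper alternates electric and magnetic sub-updates with the
fourth-order Yoshida weights (stage weights `c`, `d` with `sum(c) = sum(d)
= 1`, palindromic symmetry, and a backward middle stage,
`w1 = 1/(2 − 2^{1/3})`, `w0 = 1 − 2 w1`); space is discretised on the
staggered Yee lattice with the fourth-order two-pair stencil
`(9/8)(f_{i+1} − f_i) − (1/24)(f_{i+2} − f_{i−1})` per cell. Conductive
tissue enters through the flux-density formulation with a conductivity
running sum; the protective layer is a collisional Drude plasma advanced by
an auxiliary current (`dJ/dt + νJ = ε0 ωp² E`). Local SAR is
`σ |E|²_peak / (2ρ)` per tissue cell, with peaks tracked over one
steady-state source period. A classic second-order Yee leapfrog
(`scheme = "fdtd22"`) is included as the baseline for comparison.

## Worked example 1: long-term cavity stability

A 120-cell PEC cavity is driven by a unit-amplitude Gaussian hard source;
both schemes run 3146 steps at Courant number 0.5, and each snapshot is
compared with the method-of-images analytic solution:

```r
library(sfdtd)
bench <- cavity1d_benchmark()
bench$summary
#>  scheme step      peak   l2_error
#>   sfdtd  436 0.9994937 0.01685472
#>   sfdtd 3146 0.9987532 0.01452534
#>  fdtd22  436 0.9944591 0.03729015
#>  fdtd22 3146 0.9774673 0.30934169
```

Reading: at iteration 436 both schemes still track the analytic waveform
(< 4% relative L2 error). By iteration 3146 the second-order baseline has
accumulated 31% L2 distortion and its peak has decayed below the 1 V/m
source amplitude, while the symplectic scheme still matches the analytic
pulse to 1.5% with its peak at 0.999 V/m. The fitted orders of accuracy
are available from `convergence_report()` (≈ 4 in space and time for the
symplectic scheme, ≈ 2 for the leapfrog control).

## Worked example 2: plasma-layer shielding at 64 MHz

The desk-scale phantom (225 × 225 cells at 4 mm) under a unit plane wave,
with the 2-cm Drude layer (`fp = 3 GHz`, collision rate `1e10 1/s`) at
increasing angular coverage:

```r
study <- sar_study(frequencies = 64e6, angles = c(0, 60, 90, 120, 180),
                   scale = "desk", mode = "tm")
study$summary
#>  frequency angle peak_sarx peak_sary  peak_sar reduction_x reduction_y
#>    6.4e+07     0 1.865e-05 8.003e-06 1.865e-05       0.000      0.0000
#>    6.4e+07    60 1.612e-05 7.796e-06 1.612e-05      13.571      2.5875
#>    6.4e+07    90 1.533e-05 7.628e-06 1.533e-05      17.779      4.6799
#>    6.4e+07   120 1.492e-05 7.408e-06 1.492e-05      19.959      7.4336
#>    6.4e+07   180 1.475e-05 6.907e-06 1.475e-05      20.904     13.6858
```

`peak_sarx` / `peak_sary` are the maxima of the SAR profiles along the
horizontal and vertical lines through the phantom centre (W/kg per 1 V/m
incident amplitude); the reduction columns are percent relative to the
unshielded run. Shielding is passive and monotone in the arc angle, the
60° layer removes ~14% of the frontal profile peak, and 90°, 120°, and
180° are within a few percent of one another — the 90° arc is the
economical choice. SAR maps are exactly mirror-symmetric about the beam
axis (to 1e-14), and repeating any run gives bit-identical fields.

## Command-line use

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/sfdtd cavity1d --out out/
Rscript inst/cli/sfdtd sar2d --freq 64 --angles 0,60,90 --scale desk --out out/
Rscript inst/cli/sfdtd converge
Rscript inst/cli/sfdtd run --config my_run.yaml
```

Outputs are plain text (CSV/TSV/JSON + a YAML config echo) with an MD5
content-hash manifest; identical runs produce identical hashes. The YAML
configuration schema is documented in `?load_config`.

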