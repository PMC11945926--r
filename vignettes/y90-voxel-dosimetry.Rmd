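---
title: "Voxel dosimetry and activity planning for intra-arterial Y-90 microbubbles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel dosimetry and activity planning for intra-arterial Y-90 microbubbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Recurrent glioblastoma is routinely re-irradiated with external photon beams,
at the price of dose to large volumes of normal brain.  An alternative is to
deliver a beta emitter directly into the tumor's arterial supply: yttrium-90
bound to a microbubble carrier lodges in the tumor vasculature and irradiates
a shell of one centimetre or less around wherever it deposits, acting as a
permanent implant (the 64 h physical half-life is short against any
biological clearance of the lodged carrier).

Planning such a treatment from imaging requires four ingredients, each of
which is a module of this package:

1. a **dose voxel kernel** (DVK): the dose delivered to each voxel of a grid
   per unit cumulated activity in the central voxel (`generate_dvk()`);
2. an **activity map**: where the administered activity sits, taken
   proportional to contrast-enhanced T1-weighted MR intensity inside the
   delineated tumor (`build_activity_map()`);
3. the **absorbed dose** by discrete convolution of cumulated activity with
   the kernel (`convolve_dose()`);
4. **radiobiology and prescription**: biologically effective dose (BED)
   under the linear-quadratic model, dose-volume histograms, and solved
   administered activities (`bed_y90()`, `compute_dvh()`,
   `prescribe_activity()`, all orchestrated by `y90_plan()`).

A synthetic phantom generator (`generate_phantom()`, `generate_cohort()`)
and a parametric external-beam comparator (`generate_vmat_like_dose()`)
close the loop so that the whole pipeline is testable without patient data.

## The dose voxel kernel

### Beta spectrum

`beta_spectrum()` tabulates the allowed-transition Fermi shape for the
Y-90 → Zr-90 decay (endpoint 2.2801 MeV, daughter Z = 40),

$$f(E) \propto p\,W\,(Q - E)^2\, F(Z, W), \qquad
  F = \frac{2\pi\eta}{1 - e^{-2\pi\eta}},\quad \eta = \frac{\alpha Z W}{p},$$

normalised by trapezoidal quadrature on 400 points.  The quadrature mean is
about 0.947 MeV.  Y-90's transition is in reality first-forbidden unique;
the allowed shape is an adequate and fully reproducible stand-in for
kernel-scale dosimetry, and any published tabulation can be swapped in
through the `density` argument, which the sampling and transport machinery
treats identically.

### Transport model

Decays originate uniformly inside the central voxel with isotropic
directions.  Electrons are transported along **straightened
condensed-history tracks**: the collision stopping power of water
(Berger–Seltzer formula, I = 75 eV, Z/A = 0.55509, no density-effect
correction) is integrated once into a range–energy table, and each particle
deposits, at every straight-line step (default one quarter of the smallest
voxel edge), the energy difference given by the residual-range lookup.
Electrons below 10 keV (configurable) deposit locally.  This neglects
multiple-scattering detours, which in reality shorten the effective
penetration somewhat; the approximation is conservative in range and
accurate in total energy, which is conserved exactly by construction.  The
transport inner loop is compiled (Rcpp); all sampling happens in R so a
single integer seed makes the kernel bitwise reproducible.

### Photon tail

Y-90's long-range dose component is dominated by bremsstrahlung.  Rather
than transporting photons, a fixed radiative-yield fraction (default 0.8% of
the emitted beta energy, the order of the radiation yield of the Y-90
spectrum in water) is deposited deterministically through an exponentially
attenuated isotropic point kernel $\mu e^{-\mu r}/(4\pi r^2)$ with an
effective attenuation coefficient of 0.12 cm$^{-1}$ (water, few hundred
keV).  Photon energy leaving the grid is tallied as escaped, not
redistributed — on the default 53³ grid roughly three quarters of the
photon energy escapes, which is physically sensible for a ~4 cm box.  Both
the yield and $\mu$ are exposed as arguments.  This model reproduces the
qualitative beta/photon crossover (beta dominates out to about 1.1 cm in
the generated kernels, which brackets the ~0.7 cm figure quoted for full
Monte Carlo kernels from the conservative side) without a photon transport
code.

### Uncertainty

Primaries are split into equal batches (default 10); the per-voxel relative
standard error comes from the batch-to-batch variance of the mean, and
`estimate_kernel_uncertainty()` extrapolates it by the $1/\sqrt{N}$ law.
At $10^6$ histories the maximum relative uncertainty within 4.8 mm of the
centre is a few percent, i.e. well below 1% when extrapolated to the
$5\times10^8$ histories of a production run.

### Units

`energy_to_dose_rate_units()` documents the full unit chain: MeV per decay
per voxel × 1.602176634·10⁻¹³ J/MeV ÷ voxel mass (unit-density water),
expressed per 10⁶ decays (1 MBq·s) in mGy, giving the kernel unit
mGy·MBq⁻¹·s⁻¹.

## Activity mapping and convolution

The surrogate assumption is deliberately minimal: within the tumor VOI,
voxel activity is administered activity × intensity / (sum of intensity over
the VOI); outside the VOI it is exactly zero.  Intensity is therefore
normalised **within the VOI only** — no background subtraction, no
windowing; a constant intensity rescaling leaves the map unchanged.
Negative intensities are clipped to zero before normalising.

Cumulated activity assumes physical decay only ($\tilde a = a/\lambda$,
$\lambda = \ln 2 / 64\,\mathrm{h}$): the lodged carrier is a permanent
implant, consistent with the BED model below.

`convolve_dose()` evaluates the dosimetry sum by FFT with zero padding (no
circular wrap-around), refuses kernels whose voxel size does not exactly
match the activity map (resampling a kernel silently would corrupt the
absolute dose scale), accumulates in double precision and tallies the
fraction of kernel-predicted dose falling outside the image instead of
redistributing it.  A triple-loop direct evaluation of the same sum serves
as the test oracle, and a uniform-activity run must reproduce the analytic
equilibrium dose (cumulated activity concentration × energy per decay ÷
mass) to 0.1%.

## Radiobiology

Two linear-quadratic BED forms are implemented:

* fractionated external beam: $BED = D\,(1 + d/(\alpha/\beta))$;
* Y-90 permanent implant:
  $BED = D\,\bigl(1 + \tfrac{\lambda}{\lambda+\mu}\tfrac{D}{\alpha/\beta}\bigr)$,
  with repair rate $\mu = \ln2/T_{rep}$.

Defaults: $\alpha/\beta$ = 10 Gy (tumor) and 2.5 Gy (normal brain),
$T_{rep}$ = 1.5 h and 2.5 h respectively, $T_{phys}$ = 64 h.  Voxelwise maps
(`bed_map()`) use tumor parameters inside the PTV and normal-tissue
parameters elsewhere.  For the comparator plan the per-voxel fraction size
is taken as $d = D_{voxel}/N$ with $N$ = 30 — the standard voxelwise LQ
convention when the fraction count, not the fraction size, is fixed.

## Prescription

`compute_dvh()` builds cumulative DVHs on a 0.1 Gy grid.  $D_p$ follows the
"largest dose received by at least fraction $p$ of the volume" convention;
on binned curves it is linearly interpolated between edges, while the
prescription solver uses the exact order statistic of the voxel doses,
which commutes exactly with activity rescaling — so the solved
$A_p = A_0\,D_{rx}/D_p(A_0)$ closes the loop to machine precision.  The
nominal simulated activity is 1 GBq.

BED matching solves for the activity at which the **mean PTV BED** of the
Y-90 plan equals the comparator's; the mean (rather than a coverage-level
BED) is the default because iso-effectiveness claims for such comparisons
are made at the level of mean target BED, and the solver also offers a
D95-level statistic.  The root is unique (BED is strictly increasing in
dose, dose linear in activity) and found by bracket expansion plus Brent's
method.

`compare_plans()` is a paired two-sided t-test on per-phantom metric
differences (significance at 0.05), with an explicit degenerate flag when
all differences are equal.

## The synthetic cohort

`phantom_spec()` defaults define the study conditions:

* grid 96³ voxels at 0.8 mm isotropic — the acquisition voxel of the
  emulated T1-weighted protocol.  The field of view is a reduced
  brain-scale box (ellipsoid semi-axes 35 × 30 × 28 mm, ~123 cm³) rather
  than a full adult head; this keeps a nine-phantom planning run desk-sized
  while preserving every quantity the analyses depend on, which are driven
  by the PTV/brain volume *ratio*, not absolute brain size.
* tumor: union of 3–7 overlapping random spheres around the centroid,
  clipped to the brain interior, taken as the voxels with the smallest
  lobed-shape field values until the requested volume is met — contiguous
  by construction (all lobes contain the centroid), irregular, and exact to
  the voxel.  A pure-sphere option exists for analytic tests.
* enhancement: log-normal within the PTV (median 3 × background, log-sd
  0.5), Gaussian background noise (sd 5 on a background of 100) clipped at
  zero.  No published within-VOI intensity statistics exist for this
  setting, so the heterogeneity magnitude is an exposed parameter, chosen
  to produce the strong dose heterogeneity characteristic of
  perfusion-weighted uptake.
* cohort: nine phantoms, PTV/normal-brain volume ratios log-spaced over
  0.005–0.15 (an order of magnitude and a half, matching the spread of
  relative tumor burden across a recurrent-GBM cohort), distinct derived
  seeds.

The comparator surrogate blurs the PTV indicator with a 6 mm Gaussian
penumbra, holds the PTV within a ±2% homogeneity ripple, adds a 10%
out-of-field base dose (entry/exit dose through the brain), and rescales to
a mean PTV dose of exactly 60 Gy in 30 fractions.  No organ-at-risk sparing
is modelled: the comparisons drawn from it (target homogeneity, mean brain
dose) only require the penumbra model.

**What the phantoms do not emulate**: MR physics (bias fields, coil
profiles), registration error, vessel/bone exclusions beyond the VOI mask
itself, perfusion kinetics, and any absolute calibration of intensity to
activity.  Consequently, passing tests demonstrate the correctness and
internal consistency of the dosimetry and prescription machinery under the
stated assumptions — not the clinical accuracy of the intensity-surrogate
assumption itself.

## Numerical choices and degenerate inputs

* FFT padding to sizes with small prime factors; sub-nanoscale negative
  round-off clipped to zero.
* Kernel/map voxel mismatch, empty VOIs, all-zero VOI intensity,
  non-positive half-lives, empty PTVs and unbracketable BED targets all
  raise immediate errors rather than propagating silently.
* The reference kernel configuration (53³ voxels, 0.8 × 0.8 × 0.78 mm) is
  available for replication, but the default planning kernel is generated
  directly on the activity grid (0.8³ mm) since convolution demands exact
  voxel agreement.
* Problem sizes used by the shipped test-suite runs: kernels at 10⁶
  histories (reference grid) and 5×10⁵ (planning grid), equilibrium checks
  at 2×10⁶, nine-phantom cohorts at 96³ voxels — sizes at which every
  stochastic acceptance margin is comfortably resolved on a single CPU.

## Known limitations

* Straight-line CSDA transport overestimates the practical range slightly
  (no angular detours) and ignores energy-loss straggling; the 99.9%
  energy radius of the generated kernel (~1.0 cm) should be read with that
  bias in mind.
* The photon tail is an attenuation model, not transport; absolute photon
  dose beyond a few centimetres is indicative only.
* Homogeneous unit-density water everywhere — no bone or air corrections.
* The comparator is a geometric surrogate; absolute normal-brain doses
  under it depend on the penumbra and base-dose parameters, and only
  direction-of-effect conclusions are drawn from them.
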