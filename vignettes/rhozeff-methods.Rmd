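---
title: "Methods: rho-Zeff tissue segmentation for kV cone-beam CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rho-Zeff tissue segmentation for kV cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhozeff)
```

## The problem

Small-animal irradiators image with cone-beam CT at around 40 kVp and treat
at around 225 kVp. In this energy range the photoelectric effect is a major
dose channel, and its cross-section grows steeply with atomic number, so
absorbed dose depends on a voxel's elemental composition as well as its mass
density. Monte Carlo dose engines therefore need every voxel mapped to a
*material* — density plus elemental mass fractions — not just to a density.

Two obstacles stand in the way. First, the classic stoichiometric
calibration, which fits a parameterized attenuation model to scanned
reference materials and then predicts the CT number of any composition, was
designed for collimated fan-beam CT; on cone-beam acquisitions the divergent
broad beam produces far more scatter, and the fitted model misses measured
CBCT numbers by large margins (this package keeps the method,
`fit_stoichiometric()`, as the baseline — on CBCT-like synthetic data its
failure shows up as large HU residuals, not from any scatter physics, which
is not modeled). Second, tissue tables list only a few dozen reference
tissues, with gaps in density–composition space far too coarse for 1–3% dose
accuracy at kV energies.

The approach implemented here sidesteps both: empirically, the CBCT number of
a material is a smooth monotonic function of the single product
$x = \rho Z_{\mathrm{eff}}$, so one cubic calibration curve plus a lattice of
artificial "dose-equivalent" tissues interpolated between the reference
tissues yields a complete material per voxel.

## The effective atomic number

Tissue tables print $Z_{\mathrm{eff}}$ without stating its defining formula,
and the common conventions disagree by several percent. The package makes the
convention explicit:

$$Z_{\mathrm{eff}} = \Big(\sum_i a_i Z_i^{\beta}\Big)^{1/\beta},$$

where $a_i$ is either the normalized mass fraction (`weighting = "mass"`) or
the normalized electron fraction $w_i Z_i / A_i$ (`weighting = "electron"`,
the classic Mayneord choice with $\beta = 2.94$).
`calibrate_zeff_definition()` grid-searches $\beta \in [2.5, 5]$ in steps of
0.01 over both weightings against a reference table; on the packaged ICRU
44/46 table the search lands on $\beta = 3.5$ with mass weighting, which
reproduces the tabulated soft-tissue values to well under 1% (RMS relative
deviation `r signif(default_zeff_definition()$rms, 2)`). That definition is
the package default. Ties break toward smaller $\beta$; calibrating on fewer
than 10 entries is allowed but flagged as under-determined.

The packaged table (`icru_tissues()`) covers 34 tissues from inflated lung
($\rho Z_{\mathrm{eff}} = 2.05$ g/cm³) to adult cortical bone (26.84 g/cm³).
Elemental compositions are transcribed from the public ICRU 44/46 body-tissue
tables; two rows whose sources could not be traced unambiguously carry
synthetic compositions constructed to be consistent with their tabulated
$(\rho, Z_{\mathrm{eff}})$ and are flagged `provenance = "synthetic"`. A few
rows' printed $\rho$, $Z_{\mathrm{eff}}$ and product disagree in the last
printed digit (the table's source presumably used unrounded inputs); the
`consistent` column marks the rows where the product is exact, and integrity
tests use only those.

## The calibration curve

`fit_hu_curve()` fits $HU = c_0 + c_1 x + c_2 x^2 + c_3 x^3$ by unweighted
ordinary least squares on at least five distinct calibration points
(one per scanned insert of known $\rho Z_{\mathrm{eff}}$). Choices worth
stating:

- **Fit direction.** HU is fitted as a function of $x$, matching how
  calibration data are plotted, and inverted numerically (bisection to
  $|\Delta HU| < 10^{-6}$). A cubic fitted in the other direction would not
  be this curve's inverse.
- **Monotonicity is checked, not enforced.** The derivative (a quadratic) is
  evaluated at the domain endpoints and its interior stationary point; a
  non-monotone fit is recorded with a warning and refuses inversion, since
  voxel assignment is meaningless on a folded curve.
- **Out-of-domain behavior.** Prediction extrapolates with a warning.
  Inversion clamps to the domain ends with a flag: CBCT artifacts (beam
  hardening, metal, air streaks) produce HU outside the calibrated range,
  and the nearest physical material is the right assignment for them.
- `r_squared` is the squared Pearson correlation between fitted and observed
  HU.

For a fully synthetic workflow, `simulated_insert_points()` generates the
calibration scan through the parameterized attenuation model
$\mu = \rho \sum_i (w_i/A_i)(K^{KN} Z_i + K^{ph} Z_i^{4.62} + K^{sca}
Z_i^{2.86})$ and $HU = 1000(\mu/\mu_{\mathrm{water}} - 1)$, with default
coefficient ratios ($K^{ph}/K^{KN} = 10^{-4}$, $K^{sca}/K^{KN} = 5\times
10^{-3}$) chosen once so the simulated scan behaves like a low-kVp
acquisition: cortical bone near +2800 HU, inflated lung near −720 HU, and a
cleanly monotonic cubic over the whole tissue range. Only coefficient ratios
matter — the overall scale and Avogadro's number cancel in the water ratio —
so fits fix $K^{KN} = 1$. The stoichiometric fit alternates a linear solve
(with the water normalization frozen) with a water renormalization, then
polishes with a full nonlinear minimization of the HU objective; the
alternating fixed point alone can sit measurably off the least-squares
optimum when residuals are large.

## The dose-equivalent tissue database

At kV energies, two materials whose $\rho Z_{\mathrm{eff}}$ differ by no more
than about 0.2 g/cm³ receive nearly the same absorbed dose, so a lattice with
that spacing is dose-wise dense enough. The default grid is
$\{2.0 + 0.2k,\ k = 0..124\}$ — 125 values from 2.0 to 26.8 g/cm³. (A span
quoted as "2 to 27 in steps of 0.2" contains 126 lattice points; with a
count of 125 one endpoint must be open, and the lower endpoint is kept since
the top interpolation is still anchored by cortical bone at 26.84.)

Each artificial tissue at target $x$ is generated by
`interpolate_tissue()`:

1. Find the two reference tissues bracketing $x$ in $\rho Z_{\mathrm{eff}}$
   (at the extreme ends the nearest pair is used with the interpolation
   weight clamped to $[0,1]$).
2. Linearly interpolate the target $Z_{\mathrm{eff}}$ and all elemental mass
   fractions with the same weight.
3. Recompute $Z_{\mathrm{eff}}$ from the interpolated fractions (the power
   law is nonlinear, so the two differ slightly).
4. While the recomputed value deviates from the interpolated target by more
   than 5% (relative), transfer 0.001 of mass within a regime-dependent
   element pair — carbon/oxygen for targets below 10 g/cm³,
   phosphorus/calcium at or above — raising the higher-Z member when
   $Z_{\mathrm{eff}}$ is too low. The transfer conserves the pair's total
   mass; if the donor is exhausted, only the recipient moves and hydrogen
   compensates. A cap of 2000 iterations turns pathological targets into
   diagnosable errors rather than hangs.
5. Restore the mass-fraction sum to exactly 1 through hydrogen, whose
   $Z = 1$ has negligible leverage on $Z_{\mathrm{eff}}$; driving hydrogen
   negative is an error, not a silent clamp.
6. Deduce the density $\rho = x / Z_{\mathrm{eff}}$.

With the packaged table the 5% band never triggers the adjustment loop —
linear mixing already lands within a fraction of a percent — but the loop is
exercised (and needed) under tighter tolerances. Two properties worth noting:
the generated compositions are bit-reproducible (no randomness anywhere in
the generator), and $Z_{\mathrm{eff}}$ along the grid *tracks the reference
table*, which itself is not monotone in $\rho Z_{\mathrm{eff}}$ (adipose has
a higher $Z_{\mathrm{eff}}$ than the slightly denser yellow marrow), so the
generated $Z_{\mathrm{eff}}$ sequence legitimately dips in places. These
tissues are dose-equivalence constructs; they have no anatomical meaning.

`assign_hu_intervals()` attaches to each tissue the half-open interval
$[lo, hi)$ whose boundaries are midpoints between consecutive tissues'
predicted HU; the first interval extends down to −1000 and the last up to
32767, so the intervals tile the whole HU axis with deterministic boundary
behavior (ties go up).

## Segmentation

`segment_volume()` is a pure per-voxel map: HU below the air threshold →
label 0; otherwise the unique tissue whose interval contains the value.
Volumes are axis-aligned (no orientation matrix; world = origin + index ×
spacing), which holds for the CBCT exports this workflow targets. The air
rule exists because reference tissue tables start at inflated lung while
mice contain true air (cavities, scanner background): the default threshold
of −850 HU sits between air at −1000 and the ≈ −720 HU the default curve
assigns to the lightest tissue. The right value depends on the calibration
curve in use, so it is a parameter; setting it above the lightest tissue's
HU draws a warning. A mask-based `override_labels()` is provided for manual
artifact handling (e.g. dense objects whose centers suffer beam hardening)
instead of any automatic correction.

`export_mc_materials()` writes a GATE/Geant4-style material database (name,
density, per-element mass fractions at fixed 6-decimal rounding, with the
rounding residue absorbed into the largest fraction so every record sums to
1) and the matching contiguous HU-range file.

## Gamma comparison

`gamma_index()` implements the standard 2D dose-comparison metric: for every
reference pixel above the evaluation isodose (default 10% of the reference
maximum), $\gamma$ is the minimum over nearby target positions of
$\sqrt{(\Delta D / (dd \cdot D_{norm}/100))^2 + (d / dta)^2}$. Numerical
choices:

- **Global normalization to the reference maximum.** Both planes are
  compared on the reference's absolute scale; the criterion dose is a
  percentage of that maximum.
- **Search.** Offsets on a $dta/10$ grid within radius $3 \cdot dta$,
  evaluated by bilinear interpolation of the target (reference pixels are
  never interpolated), followed by a local refinement pass (window of ±3
  coarse steps at $dta/150$ around each pixel's best coarse offset). The
  refinement matters: a single coarse pass carries a quantization error that
  is first-order in the dose gradient and can exceed 0.2 in $\gamma$ where
  gradients are steep relative to the dose criterion. With refinement the
  implementation agrees with an exhaustive $dta/100$ brute-force search to
  better than 0.02 on the smooth random fields used in the tests.
- Unequal grids are handled by resampling the target only.
  `masked_diff_stats()` reports max/mean absolute relative difference and
  max absolute difference inside a reference isodose mask (default 80%).

## The synthetic phantom generator

`make_default_phantoms()` provides two deterministic specs: an eight-insert
cylinder battery spanning soft tissue to cortical bone, and a mouse-like
phantom (ellipsoidal soft-tissue body, two inflated-lung pockets, two
femur-like bone rods in air). `rasterize_phantom()` labels a voxel by the
last region containing its center — no partial-volume mixing, so ground
truth is unambiguous. `simulate_hu()` is the forward model: each voxel's HU
is the calibration curve evaluated at its material's $\rho Z_{\mathrm{eff}}$
plus additive Gaussian noise (air voxels take −1000 + noise). Acquisition
noise on this scanner class is bounded by about 30 HU, so $\sigma \in
[0, 30]$ is the realistic range; Gaussian is the minimal model — $\sigma$ is
a parameter, not a claim about the scanner's noise law.

What the generator deliberately does **not** emulate: beam hardening,
scatter, reconstruction artifacts, partial-volume voxels, or any
projection/reconstruction physics. Passing end-to-end tests therefore shows
that calibration, database construction and interval assignment are mutually
consistent and robust to additive HU noise — not that the method survives
real CBCT artifacts, which is precisely why the air threshold, the override
mask, and inversion clamping exist as escape hatches on real data.

## Test conditions and problem sizes

The test suite regenerates everything from code: phantoms at 0.4–0.5 mm
voxels (tens of thousands of voxels), the noisy-segmentation check across 20
noise seeds at $\sigma = 10$ HU, gamma oracle comparisons on 20×20 planes at
0.2 mm spacing with the 4% / 0.3 mm criteria, and calibration fits on 11
insert points — sizes chosen so the full suite runs in a few minutes while
every property is exercised at the tolerances stated above. The
measured-data claims of the underlying approach (scanner calibration
quality, film-vs-Monte-Carlo dose agreement) require physical hardware and
are out of scope; the package ships the machinery to perform those
comparisons, validated against closed forms and brute-force oracles on
synthetic data.

## Known limitations

- No scatter or beam-hardening correction of the input volume; dense-object
  centers need the override mask on real data.
- The cubic is fitted unweighted; no uncertainty propagation on fitted
  coefficients.
- NIfTI support assumes an identity orientation matrix.
- The stoichiometric module reproduces the *form* of the fan-beam
  calibration; it contains no cone-beam scatter physics, so its failure on
  CBCT data appears only as large residuals when such data are supplied.
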