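---
title: "Methods: coffee drying kinetics and hyperspectral cup-score chemometrics"
author: "beandry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coffee drying kinetics and hyperspectral cup-score chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beandry)
```

This vignette is the package's own account of its models, the
parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real measurements.

## 1. Drying kinetics

### Model

Thin-layer convective drying of a coffee bean is modeled as Fickian
diffusion in a sphere of radius $L$ with a convective (Robin) surface
condition. The dimensionless moisture ratio is the eigenfunction
series

$$\phi(x/L,\,\mathrm{Fo}) \;=\; \sum_{n\ge 1}
  \frac{2\,(\sin\mu_n - \mu_n\cos\mu_n)}{\mu_n - \sin\mu_n\cos\mu_n}\,
  \frac{\sin(\mu_n x/L)}{\mu_n x/L}\;
  e^{-\mu_n^2\,\mathrm{Fo}},$$

with Fourier number $\mathrm{Fo} = D_\mathrm{eff}\,t/L^2$ and
eigenvalues $\mu_n$ solving $1-\mu\cot\mu = \mathrm{Bi}$, one root
per interval $((n-1)\pi,\,n\pi)$. `seriesPhi()` evaluates this sum;
`rootsForBiot()` finds the eigenvalues by bisection inside each
bracket (the function is strictly increasing between its vertical
asymptotes at multiples of $\pi$).

At large Fourier number the first term dominates; taking logs at the
surface $x/L = 1$ gives a straight line in time whose slope is
$a = -\mu^2 D_\mathrm{eff}/L^2$ and whose intercept is
$b(\mu) = \ln\!\big[2\sin\mu\,(\sin\mu-\mu\cos\mu) /
(\mu\,(\mu - \sin\mu\cos\mu))\big]$. `estimateTransport()` chains the
inverse steps: `moistureRatio()` (log-ratio against time in seconds),
`linearizedFit()` (ordinary least squares), `solveMuFromIntercept()`
(bisection of $b(\mu) = b$), `biotFromMu()`, `dEffFromSlope()` and
`hmFromBiot()`.

Assumptions inherited from the model, and therefore limitations of
the package: isothermal bean, constant diffusivity, spherical
geometry, no shrinkage. Only the analytical sphere solution is
implemented; finite-element or moisture-dependent-diffusivity models
are out of scope.

### Parameters and units

* **Characteristic length `radiusL`** (m). The reference tables this
  package regenerates are mutually consistent only with
  $L = 3.968\times10^{-4}$ m, although the accompanying text of the
  source material prints $L = 0.003968$ m; the two differ by a factor
  of 100 and the package does not guess which is the physically
  measured radius. `radiusL` is therefore a required, explicit
  argument everywhere, and $3.968\times10^{-4}$ m is used in the
  fixtures because it reproduces the tables.
* **Time units.** Drying times are recorded in hours but slopes of
  order $10^{-5}$ are only dimensionally consistent with seconds, so
  `moistureRatio()` converts h to s before fitting; $D_\mathrm{eff}$
  then comes out in m²/s.
* **Moisture basis.** Curves carry a wet/dry basis flag;
  `convertBasis()` interconverts ($d = 100w/(100-w)$), and the ratio
  computation works on a dry basis.

### Numerical choices

* **Bisection.** Eigenvalue brackets use $\delta = 10^{-9}$ at the
  asymptotes. The intercept inversion brackets on
  $(10^{-6}, \pi-10^{-6})$ instead: below $\mu \approx 10^{-6}$ the
  factor $\sin\mu - \mu\cos\mu \sim \mu^3/3$ is pure cancellation
  noise in double precision, and all physically observed roots are
  $O(1)$. Iteration stops when the interval is narrower than
  $10^{-12}$ or after 60 halvings, whichever comes first (about 50
  halvings are needed from the full interval).
* **Critical moisture.** The transition between the constant-rate and
  falling-rate periods is found by exhaustive two-segment
  piecewise-linear least squares on the rate-vs-moisture series
  (`criticalMoisture()`): every contiguous interior partition with at
  least two points per segment is fitted and the minimum-SSE
  breakpoint is reported, guarded by the requirement that the
  segmented fit reduce the single-line SSE by at least a factor of 2
  (otherwise "no transition"). This is deterministic and directly
  testable against planted breakpoints.
* **Equilibrium moisture.** Defined as the series minimum; the
  plateau entry time is the first sample within 0.1 % moisture of
  that minimum.
* **Points at or below equilibrium.** Measurement noise can cross
  $M_\mathrm{eq}$; such points have no defined log ratio and are
  dropped with a warning rather than raising an error.
* **First-term validity.** `estimateTransport(minFourier = )` can
  restrict the fit to $\mathrm{Fo}$ above a cutoff; with multi-term
  synthetic curves the tests show the single-term inversion recovers
  $D_\mathrm{eff}$ within 2 % when fitting $\mathrm{Fo} > 0.2$, and
  essentially exactly on single-term curves.

## 2. Arrhenius temperature dependence

`fitArrhenius()` regresses $\ln v$ on $1/(T+273.15)$ by ordinary
least squares; $E_a = -\mathrm{slope}\cdot R/1000$ kJ/mol with
$R = 8.31446$ J/mol/K fixed, and the pre-exponential factor is
$\exp(\mathrm{intercept})$ — always computed from the intercept, since
a printed pre-factor in the reference material disagrees with its own
intercept by two orders of magnitude while the downstream prediction
table is consistent with the intercept. Both fitting paths are
exposed: refitting re-estimated transport values (what
`runKineticsWorkflow()` does end-to-end) and fitting the printed
reference values directly (what the regression tests do), which
isolates rounding drift of roughly 0.1 % between the two.

## 3. Hyperspectral preprocessing

* **Reflectance correction** (`correctReflectance()`):
  $R_c = (S-D)/(W-D)$ per pixel and band. Push-broom line scanners
  calibrate per column, so $1\times W\times B$ line references are
  broadcast over rows. Pixels with $W-D \le \varepsilon$ are masked
  `NA`; values below dark are clipped to 0.
* **ROI segmentation** (`segmentROI()`): no specific thresholding
  method is mandated by the workflow this package implements, so Otsu
  on the band-mean image was chosen for determinism and testability
  (via EBImage); the threshold is attached to the mask. Foreground
  defaults to the darker class (beans on a bright stage), invertible
  by flag; uniform images and empty foregrounds are errors.
* **Median spectrum** (`medianProfile()`): per-band median over the
  masked pixels; invalid pixels are excluded, never zero-filled.
* **Absorbance** (`toAbsorbance()`): the Beer–Lambert convention
  $A=-\log_{10}R$ is the default; a natural-log switch exists because
  downstream centered regression is equivariant to the log base.
  Zero reflectances are floored at $10^{-6}$ with a warning.
* **Savitzky–Golay** (`sgSmooth()`): each point is replaced by the
  value of the least-squares polynomial of degree $N$ (default 2)
  over the $2M+1$ surrounding points (default 23). At the edges the
  window is truncated and the polynomial refitted, a policy chosen
  over mirror padding because it preserves exactness on polynomials
  of degree $\le N$ everywhere. Interior points equal the classical
  convolution weights (and the reference implementation in the
  `signal` package, which the tests cross-check).
* **Normalization** is deliberately not applied by default: the
  workflow this package follows mentions an unspecified
  normalization; rather than guess among SNV/min–max/area variants,
  spectra pass through smoothing only, and any normalization can be
  applied by the caller before `fitPLSR()`.

## 4. PLSR and wavelength selection

`fitPLSR()` implements NIPALS with mean-centering of $X$ and $y$ and
no variance scaling (classic chemometrics practice for spectra on a
common scale), deflating both matrices per component and assembling
$\beta = W(P^\top W)^{-1}q$. With as many components as the rank of
$X$ the fit equals ordinary least squares, which the tests use as an
oracle. Successive score vectors are mutually orthogonal by
construction; the tests assert it.

* **Latent dimension.** `selectNLV()` computes
  $Q^2(k) = 1-\mathrm{PRESS}(k)/\mathrm{TSS}$ over a seeded 5-fold
  partition and returns the smallest $k$ attaining the maximum.
  Values within `q2Tol` $=10^{-3}$ of the maximum are treated as
  ties: cross-validated curves flatten near their optimum, and
  without the tolerance, hairline noise-driven improvements
  occasionally inflate the selected dimension. A maximum $Q^2 \le 0$
  means no component predicts better than the mean; the function
  warns and reports 0.
* **Final model order.** The end-to-end workflow caps the dimension
  at `max_lv` (default 10) and reports VIP and loadings from the
  fitted model; interpretation plots conventionally restrict to the
  first two components, and `influentialLoadings()` defaults to
  those with an absolute-loading threshold of 0.1.
* **VIP.** No VIP formula is mandated by the source workflow; the
  standard Wold VIP is used:
  $\mathrm{VIP}_j = \sqrt{p\sum_k SS_k\,w_{jk}^2 / \sum_k SS_k}$ with
  $SS_k = q_k^2\,t_k^\top t_k$ the response variance explained by
  component $k$. Its mean square is exactly 1, giving the usual
  VIP > 1 influence rule.
* **Validation protocol.** `stratifiedSplit()` assigns
  round-half-up$(0.7\,n)$ samples per temperature stratum to
  calibration (capped at $n-1$ so every stratum validates),
  deterministically per seed. `modelMetrics()` reports $r^2$, RMSE
  and RPD $=\mathrm{SD}/\mathrm{RMSE}$.
* **Fixed-coefficient score model.** `cupScoreModel()` evaluates the
  published two-component linear map from absorbance at 480, 600,
  720 and 940 nm to cup score exactly as printed (intercept 83.14).
  It is implemented as a standalone evaluator, not derived from
  `fitPLSR()`: how its two 4-wavelength components relate to a
  full-spectrum 5-component model is not documented in the source
  material, and the package does not speculate.
* **Sensory ANOVA.** `anovaOneWay()` delegates to the classical
  equal-variance one-way decomposition (`stats::oneway.test`); the
  degenerate all-identical case is reported as $F=0$, $p=1$. The
  replicate unit (replicate means vs individual taster scores) is
  left to the caller, who passes explicit groups.

## 5. Synthetic generators

The generators emulate the statistical structure the analysis
assumes, with defaults fixed at the study conditions they stand in
for; they are pure functions of their arguments, including the seed.

* **Drying curves** (`simDryingCurve()`): forward evaluation of the
  series solution at the surface, defaults: initial moisture 45 % wet
  basis (81.82 % dry), equilibrium near 12 % wet basis (13.64 % dry),
  samples every 2 h, 52 h duration, and the 30 °C transport truth.
  Noise is Gaussian on moisture — the measurement domain of a grain
  moisture meter — not on the log ratio. Single-term curves start at
  the first positive sampling time because the truncated series does
  not satisfy the initial condition at the surface; multi-term
  curves start at $t=0$ with $M=M_0$ exactly.
* **Score-linked spectra** (`simSpectraSet()`, `simHyperCubes()`):
  cup scores are drawn from $N(83.4, 1.5^2)$ truncated to $[80, 88]$,
  matching the observed score distribution. Gaussian absorbance
  peaks (FWHM 30 nm — wide enough to survive the default 23-point
  smoothing on the ~5.4 nm band grid) are planted at the grid bands
  nearest 480, 600, 720 and 940 nm, and their post-smoothing center
  values are set to invert `cupScoreModel()` exactly for the drawn
  score. Because the printed model's gradient norm is only ~0.1 cup
  points per absorbance unit, exact inversion forces center
  absorbances around 32 with excursions of roughly ±25 — far outside
  any physical range. The generators therefore target statistical
  structure, not radiometric realism, and two further choices follow
  from this: the score-linked excursion runs along an
  equal-magnitude direction (signs matching the gradient) so that
  all four bands carry comparable score-driven variance rather than
  concentrating it on the highest-gradient band, and the synthetic
  dark frame is exactly zero so that reflectances as small as
  $10^{-60}$ survive the raw-signal round trip in double precision.
  Amplitudes are pre-compensated for the measured Savitzky–Golay
  center attenuation (0.539 for these settings), making the
  noiseless preprocess-and-score round trip exact to well under 0.01
  cup points.
* **Sensory tables** (`simSensoryTable()`): seeded Gaussian draws
  around per-temperature means (83.2, 83.5, 83.6, 83.26) with SDs of
  0.88–1.71 cup points, three replicates per temperature, clipped to
  the valid score range.

What passing tests on these data do **not** show: real spectra carry
scatter effects, instrument drift, band-to-band correlation and far
weaker score linkage than the planted structure, so the near-perfect
synthetic calibration metrics are an identifiability check, not a
performance claim; likewise, recovery of planted transport
parameters demonstrates correctness of the inversion, not accuracy
under model misspecification (non-spherical beans, shrinkage,
moisture-dependent diffusivity).

## 6. Problem sizes and tolerances in the test suite

The suite fits on a single CPU in well under a minute by choice of
problem size: spectra sets of 48–80 samples × 112 bands, cubes of
32 × 32 pixels, 100-seed Monte-Carlo loops for noisy-curve recovery
(tolerance 15 %, calibrated once and frozen) and dimension selection,
200 seeds for the smoothing variance factor (5 %) and the sensory
ANOVA consistency check (non-significant in ≥ 95 % of seeds).
Reference-table regeneration asserts 4-significant-figure agreement
for the eigenvalues and Biot numbers, ~0.2 % for the diffusivity and
mass-transfer columns (the printed reference values carry an internal
inconsistency at 30 °C of about 0.1 %, documented in the tests),
0.5 % for activation energies and 3 significant figures for the
predicted-coefficient table.

## 7. Known limitations

* The sphere solution is the only forward model; no shrinkage,
  non-isothermal or variable-diffusivity variants.
* ROI segmentation assumes a bimodal brightness histogram; scenes
  without clear sample/background contrast are rejected rather than
  segmented heuristically.
* The ENVI reader supports float/double BIL/BIP/BSQ images, which
  covers the common push-broom exports, but not integer types or
  BIL-with-offset layouts.
* `cupScoreModel()` extrapolates linearly for any absorbance input;
  it is a published fixed map, and no applicability domain is
  enforced.
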