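---
title: "Methods: quantifying core-shell tumor architecture from Q-space MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying core-shell tumor architecture from Q-space MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

`qsarch` treats a tumor as a field of locally oriented cell populations
and asks how far that orientation *coheres across space*. The chain is:
diffusion-weighted signal → per-voxel orientation distribution →
streamlines → tract-length statistics → survival association.

## Spin distribution functions (GQI)

For a voxel with signals $S_i$ acquired at b-values $b_i$ along unit
gradients $\hat g_i$, the spin distribution function evaluated along a
unit direction $\hat u$ is

$$\psi(\hat u) \;=\; \sum_i S_i \,
  \mathrm{sinc}\!\left( L_\Delta \sqrt{6 D_0 b_i}\,
  \langle \hat g_i, \hat u\rangle \right),
  \qquad \mathrm{sinc}(x) = \sin(x)/x,\ \mathrm{sinc}(0) = 1 .$$

This is the "GQI1" variant: the kernel acts on signal values, not on
squared signals. The sampling-length ratio defaults to
$L_\Delta = 1.25$, the standard in-vivo choice, and
$D_0 = 2.5\times10^{-3}\,\mathrm{mm^2/s}$ is the free-water diffusivity
at body temperature. Both are exposed in `recon_config()`. Because the
kernel argument is odd in $\hat u$ and sinc is even, $\psi$ is
antipodally symmetric by construction; the implementation additionally
mirrors one hemisphere of the evaluated values onto the other so that
the symmetry holds *bitwise* (optimized BLAS may otherwise round
identical columns differently).

Key assumptions: single-shell sampling adequately constrains
orientation (≥ 6 directions enforced, 27–64 typical); signal units are
arbitrary (all orientation statistics are scale-invariant after QA
normalization); no deconvolution sharpening is applied.

## Tessellation and peaks

$\psi$ is evaluated on a subdivided icosahedron
(`tessellate_sphere()`, $10\cdot4^L + 2$ vertices). The default level
$L = 3$ (642 vertices, maximum edge ≈ 9.4°) resolves directions about
four times finer than the 35° turning threshold while keeping the
kernel matrix small; level 2 (162 vertices, ≈ 19°) is used in the
oracle-equivalence tests where only values, not directions, matter.

A vertex is a peak iff its value strictly exceeds all its neighbours';
antipodal duplicates collapse to one direction; at most three peaks are
kept per voxel. Quantitative anisotropy (QA) of a peak is its value
minus the voxel's ODF minimum, scaled by the maximum such difference
over the masked region, so QA ∈ [0, 1] regardless of signal units. The
default peak-acceptance and tracking-termination threshold is QA ≥
0.05: an isotropic voxel's residual noise peaks fall well below it,
while genuine fiber peaks in the phantoms sit far above. A constant
ODF has no strict maximum and therefore no peaks — such voxels (and
voxels with identically zero signal, flagged degenerate) terminate
entering streamlines and are never seeded.

## Deterministic tractography

From every seed the tracker walks bidirectionally in steps of
`step_size_mm` (default 1 mm at human scale, 0.1 mm at rat scale,
matching the scale of the tract-point averaging used for the tumor
centre). At each step the peak of the *nearest voxel* that minimizes
the turning angle is followed, its sign resolved toward the direction
of travel. A half-track terminates when

* the best turning angle exceeds `angle_threshold_deg` (default 35°),
* the followed peak's QA is below `qa_termination_threshold`,
* the point leaves the peak field (mask or grid), or
* the shared length budget is spent.

The forward half runs first against the full `max_length_mm` budget
(55 mm human, 25 mm rat — the analyzed length domain); the backward
half may spend only the remainder, so a concatenated streamline never
exceeds the cap. An earlier per-half cap of `max_length / 2` was
rejected because single-sided tracks then pile up at half the cap and
fabricate a spurious mid-histogram mode. Ties between equally angled
peaks resolve to the highest-QA peak, making the procedure fully
deterministic: identical inputs give bitwise-identical tractograms.
Streamlines shorter than `min_length_mm` (default 1 mm) are discarded.

Nearest-voxel lookup (no trilinear interpolation of the ODF field) is a
deliberate simplification: it is deterministic, cheap, and adequate at
phantom resolution; interpolation is a possible extension. Euler
stepping on curved fields drifts outward by ≈ step²/(2ρ) per step on a
circle of radius ρ; at the default step and phantom curvatures this is
fractions of a millimetre over a full track and is absorbed by the
peritumoral capsule (below).

## Architecture metrics

* **Length bands.** Human: core 1–20 mm, shell 25–55 mm (the 20–25 mm
  gap belongs to neither); rat: 1–5 / 6–25 mm. Bounds inclusive.
* **c/s ratio** = mean core-band length ÷ mean shell-band length. The
  ratio of band means is the reading consistent with the metric's
  observed directionality (high c/s ↔ less necrosis ↔ longer survival);
  count- and volume-based summaries are also reported per band but are
  not the headline metric. An empty band flags the result and reports
  `NA`, never 0.
* **Tumor centre** = unweighted mean of all tract points after
  arc-length resampling at the tracking step, so long tracts do not
  dominate through denser vertices. Both endpoints are always retained
  when resampling.
* **Ring profile.** Tract points within an axial slab (|z − z_c| ≤ 20%
  of the tract set's z half-extent) are recentred; with
  $r_t=\sqrt{x^2+y^2}$ and $R = \max r_t$, the four radii
  $r_i = R\sqrt{i/4}$ bound annuli of exactly equal area. A tract joins
  every ring whose annulus contains at least one of its slab points
  (binary membership, counted once per ring), so ring populations
  overlap for crossing tracts and ring means are not independent —
  the profile is a descriptive gradient, not four independent samples.
  Rings are circular; an elliptical normalization of x, y by the slab
  half-extents is available behind a flag but off by default, because
  the point-radius formula above is circular.
* **Bi-Gaussian mixture.** A two-component univariate EM
  (`fit_bigaussian()`), initialized deterministically by splitting at
  the median (each half supplies a mean and sd), convergence when the
  log-likelihood gain drops below `tol` (1e-8), variances floored at
  $10^{-6}\cdot\mathrm{range}^2$ (hitting the floor flags the fit
  degenerate; all-identical data short-circuits to a flagged
  single-component answer). Components are reported sorted by
  ascending mean. `mclust` serves as an independent cross-check in the
  test suite, never as the implementation.
* **Histogram modes.** Bimodality is assessed on 3-bin-smoothed counts,
  but a candidate maximum only counts as a mode if the valley
  separating it from its neighbour dips below half the smaller peak.
  Plain strict-maximum counting would report ±1-count Poisson wiggles
  on a monotone flank as modes.

## Survival association

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
fits go through the `survival` package behind the module's interface.
Two hazard-ratio estimators are reported deliberately:

* `logrank_test()` returns the KM-plot convention
  $\mathrm{HR} = (O_A/E_A)/(O_B/E_B)$ with a log-scale CI. Because the
  expectations are computed under the null, this form is *conservative*
  (biased toward 1) for effects far from unity — at a true HR of ~3.8
  with 31 subjects per arm it recovers ≈ 3.0 on average, a property the
  test suite asserts.
* `cox_fit()` (Breslow ties, Newton–Raphson, 50-iteration cap,
  collinearity and non-convergence flagged) provides the consistent
  estimate; hazard-ratio *recovery* studies therefore use
  $\exp(\hat\beta)$, which recovers the generating HR to within a few
  percent at the same design.

`median_split()` orders values (ties broken by original position) and
assigns the first ⌈n/2⌉ to the low group: with distinct values this is
exactly the below/above-median split, and it always yields groups
differing by at most one — including the 31/31 split of a 62-subject
cohort. A strict "all ties go low" rule cannot simultaneously guarantee
balanced groups, so balance wins. Subjects surviving less than one
week can be excluded via `exclude_short_survivors()` (off by default —
synthetic cohorts have no data-entry artifacts). Pooling cohorts whose
tract metrics come from different scanners uses `normalize_cs_to()`
(rescale one cohort's c/s ratios to the other's mean).

# The synthetic data generators

## What the phantom emulates

`build_core_shell_phantom()` synthesizes a spherical tumor in a 32³,
1 mm grid imaged with 27 electrostatic-repulsion directions plus one b0
at b = 1200 s/mm² and Rician noise at SNR 20 (magnitude-MR model:
$\sqrt{(S+n_1)^2+n_2^2}$, noise sd = mean b0 signal / SNR):

* **Core** (r ≤ 5 mm): i.i.d. random per-voxel orientations, low FA
  (0.15), elevated diffusivity (1.5×10⁻³ mm²/s) — necrosis-like free
  diffusion with no spatial coherence, so streamlines die on the 35°
  rule within a voxel or two. `core_coherence` ∈ [0, 1] mixes the
  circumferential field into the core for disorganization sweeps.
* **Shell** (5 < r ≤ 12 mm): prolate tensors (FA 0.7, MD
  0.8×10⁻³ mm²/s) tangent to horizontal circles around the tumor
  centre — a continuous field along which streamlines run tens of mm.
  Random orientation jitter decays linearly from `shell_jitter_max`
  (0.5) at the core boundary to `shell_jitter_min` (0.15) at the outer
  capsule edge, giving a *radial coherence gradient*: alignment, and
  hence tract length, increases toward the proliferative periphery.
  This gradient is what the ring profile detects; a spatially uniform
  shell would produce flat ring means by construction.
* **Capsule** (12 < r ≤ 15 mm): a peritumoral rim of tangentially
  oriented fibers (FA 0.55), emulating parenchyma displaced by the
  expanding mass. Reconstruction and tracking run over tumor +
  capsule while seeding and labels stay confined to the tumor, so
  rim-seeded tracts are not artificially cut at the voxelized tumor
  boundary — mirroring clinical tracking, which is not confined to the
  tumor ROI.
* **Background**: isotropic (MD 0.8×10⁻³), or a uniform +x bundle for
  control experiments.

No reported diffusivity values exist for these tumor compartments; the
numbers above are generic DWI-literature magnitudes and are exposed in
`phantom_spec()`. Tensor eigenvalues are solved from (FA, MD) by root
finding; everything (gradient directions, core orientations, jitter,
noise) derives from `spec$seed`, making the phantom a pure function of
its spec.

What the phantom does **not** emulate: brain anatomy and white-matter
background tracts, mass effect and edema, eddy-current/motion
artifacts, multi-shell acquisitions, partial-volume mixtures at
compartment boundaries, and non-spherical tumor shapes. Passing the
recovery tests therefore demonstrates that the pipeline measures the
architecture the phantom contains — not that it segments or handles
real clinical images, which additionally require a tumor mask supplied
by the user (how such masks are drawn clinically is outside the
package's scope).

## Cohorts

`simulate_cohort()` draws c/s ratios from a truncated normal, event
times from exponentials with hazard
$h_i = h_0 \exp(\beta\,\mathrm{cs}_i)$ (exponential chosen over
Weibull so the generating hazard ratio has closed form; a Weibull
shape would be a config extension), independent exponential censoring
with its rate tuned by root finding so the *expected* censored
fraction hits the target, and a necrosis fraction linear in cs with
Gaussian noise, truncated to [0, 1] — reproducing the observed
anti-correlation without claiming its coefficients. Covariates (age,
KPS, IDH status) are generated but carry no effect by default.
`simulate_survival_groups()` is the two-arm special case with an
exactly known group hazard ratio, used for recovery studies.

# Study conditions and problem sizes

The full-scale recovery study (the acceptance suite) uses: the default
32³ phantom at SNR 20 with 4 seeds per tumor voxel (~29,000
streamlines); a three-level core-disorganization sweep
(`core_coherence` 0.9 / 0.6 / 0.0) run as a *paired* design — all
levels share one base seed so the comparison isolates the coherence
effect; mixture recovery on 10,000 draws (component sd set to 15% of
the component separation, draws truncated to positive lengths —
tract lengths are positive by definition, and at ≥ 2.6 sd above zero
the truncation shifts means by well under the 2% recovery band);
hazard-ratio recovery over 200 cohorts of 62 subjects (~18% censored);
and null calibration of the log-rank test over 1000 cohorts. Unit
tests use 22³ phantoms with proportionally smaller radii.

# Known limitations

* Nearest-voxel peak lookup and Euler stepping limit geometric
  fidelity at high curvature; the capsule absorbs the resulting
  boundary drift in phantoms but real data near sharp mask edges will
  lose rim tracts.
* The c/s ratio is undefined when either band is empty; very small
  tumors (shell thinner than a voxel) are rejected at phantom
  construction and will be equally problematic on real masks.
* Ring means share tracts and are not independent; treat the profile
  as a gradient summary, not as four independent measurements.
* The O/E hazard-ratio convention understates large effects; both
  estimators are reported so the choice is explicit.
* TRK files are written in world-mm coordinates with the source affine
  in the header; tools expecting voxel-scaled TRK coordinates need the
  affine applied.
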