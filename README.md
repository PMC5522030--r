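# qsarch: tumor architecture from generalized Q-space imaging

Glioblastoma is structurally heterogeneous: a necrotic, disorganized
central region is typically wrapped in a shell of densely packed, aligned
tumor cells. `qsarch` quantifies that architecture non-invasively from
multi-direction diffusion-weighted MRI and links it to patient outcome.
It is written for imaging scientists who want a self-contained, fully
synthetic-testable implementation of the analysis chain:

1. **GQI reconstruction** — per voxel, the spin distribution function
   (SDF) over unit directions *û* is the sinc-kernel Q-space summation

   ψ(û) = Σᵢ Sᵢ · sinc( L_Δ √(6 D₀ bᵢ) ⟨ĝᵢ, û⟩ ),

   with diffusion sampling length ratio L_Δ = 1.25, free-water reference
   diffusivity D₀ = 2.5×10⁻³ mm²/s, signal Sᵢ, b-value bᵢ and gradient
   direction ĝᵢ. The SDF is evaluated on a subdivided icosahedron and up
   to three peaks per voxel are kept with quantitative anisotropy
   QA = (peak value − ODF minimum), normalized to [0, 1] over the mask.
2. **Deterministic tractography** — bidirectional streamlines follow the
   per-voxel peak minimizing the turning angle, terminating beyond a
   35° threshold, below a QA floor, outside the mask, or at the length
   cap; tract length is the polyline arc length in mm.
3. **Architecture metrics** — tract-length histogram and two-component
   Gaussian mixture (EM); tumor centre from arc-length-resampled tract
   points; equal-area concentric rings rᵢ = R√(i/4) with per-ring mean
   tract length; core/shell tract populations by length filters
   (human 1–20 mm core, 25–55 mm shell; rat 1–5 / 6–25 mm) and the
   **c/s ratio** = mean core-band length ÷ mean shell-band length.
4. **Survival association** — Kaplan–Meier curves, log-rank test with
   the O/E hazard-ratio convention, median (50%) splits, Cox
   proportional-hazards fits (Breslow ties) and ordinary least squares
   for correlation panels.
5. **Synthetic ground truth** — core-shell DWI phantoms (circumferential
   shell with a radial coherence gradient, disorganized core, Rician
   noise) and survival cohorts whose log hazard is linear in the c/s
   ratio, so every stage is validated against known truth.

## Worked example

```r
library(qsarch)
spec    <- phantom_spec(seed = 1)   # 32^3 grid, b = 1200 s/mm^2, 27 dirs + b0, SNR 20
phantom <- build_core_shell_phantom(spec)
odf     <- reconstruct_odf(phantom$dwi, phantom$tracking)
seeds   <- generate_seeds(phantom$tumor, seeds_per_voxel = 4, seed = 2)
tracts  <- track(odf, seeds, tracking_config())
print(tracts)
#> Tractogram: 28832 streamlines, length 2.0-55.0 mm (mean 7.03)

compute_architecture(tracts)
#> Architecture: core 5.2769 mm (n=27132), shell 39.6649 mm (n=1158), c/s ratio 0.13304

ring_profile(tracts, tumor_center(tracts, resample_step_mm = 1))
#> Ring profile: R = 15.61 mm
#>   ring 1 (r <= 7.80): 5467 tracts, mean length 3.16 mm
#>   ring 2 (r <= 11.04): 6248 tracts, mean length 7.33 mm
#>   ring 3 (r <= 13.52): 2648 tracts, mean length 15.86 mm
#>   ring 4 (r <= 15.61): 216 tracts, mean length 43.83 mm
```

The short core-band mean against the long shell-band mean gives a low
c/s ratio (0.133) for this deliberately disorganized-core phantom, and
the ring means increase monotonically from centre to rim — the radial
alignment gradient the method is designed to detect. Coupling the
metric to outcome:

```r
cohort <- simulate_cohort(cohort_spec(n_subjects = 62, seed = 3))
split  <- median_split(cohort$cs_ratio)
logrank_test(cohort[split$low, ], cohort[split$high, ])
#> Log-rank: chisq = 6.7955, p = 0.00914; HR (O/E form) = 1.9552 [1.117, 3.421]
```

Subjects below the median c/s ratio die faster (hazard ratio ≈ 2 here),
the protective direction of a high c/s ratio.

The full five-stage experiment (simulate → reconstruct → track →
architecture → survival, with a JSON manifest of MD5-hashed artifacts)
runs from one config:

```r
run_pipeline(system.file("extdata", "demo_pipeline.yaml", package = "qsarch"),
             out_dir = "demo_out")
```

or from a shell via `Rscript inst/cli/qsarch.R run --config demo.yaml --out demo_out`.

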