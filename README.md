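# longivol

Registration-agnostic measurement of longitudinal volume change in compact
brain structures, with the full statistical evaluation battery around it.

## The problem

One-year hippocampal atrophy in Alzheimer's disease is a few percent — smaller
than the volume error of two independent segmentations. The robust way to
measure it is to segment the structure **once**, at baseline, and let a
non-linear registration's deformation field carry that segmentation to the
follow-up scan. `longivol` implements this pipeline downstream of any
registration tool that can export a dense displacement field (Elastix,
NiftyReg, ANTs, MIRTK, ...), plus everything needed to evaluate and compare
such measurements: reproducibility on back-to-back rescans, between-method
agreement, group comparisons, and trial sample-size planning.

The core quantities:

* **PVC**, percentage volume change: `(V_FU − V_BL) / V_BL × 100` (negative =
  atrophy). `V_BL` comes from a marching-cubes mesh of the baseline binary
  segmentation; `V_FU` from the same mesh with every vertex pushed through the
  displacement field `x ↦ x + u(x)` — no label resampling, no interpolation
  error accumulation. Volumes are sums of signed tetrahedra over the closed
  mesh. An independent **Jacobian route** — `∑ det(I + ∂u/∂x)` over the
  baseline mask × voxel volume — cross-checks every measurement.
* **D_Ave**, the RMS difference between paired PVC measurements: test–retest
  reproducibility when the pairs are A/B same-session rescans (true change is
  zero, so any distance is method noise), method agreement when the pairs are
  two methods on the same scans.
* **Effect size and sample size**: Cohen's `d = |μ₂ − μ₁| / σ_pooled` with the
  unweighted pooled SD `σ_pooled = √((σ₁² + σ₂²)/2)`, and
  `N = 2 (z_{α/2} + z_{1−β})² / d²` per group, rounded to the nearest integer
  (defaults α = 0.05 two-sided, power 80%: z's of 1.96 and 0.8416).

Because the reference imaging data are access-controlled, the package also
generates every input synthetically: digitized hippocampus-like shapes,
deformation fields with known regional volume change, and simulated
CTRL/MCI/AD cohorts with A/B replicates and left/right structures drawn from
bundled published group statistics (`method_reference_stats()`).

## Worked example

A digitized ellipsoid (semi-axes 12 × 8 × 6 mm, ≈ 2400 mm³, hippocampus-sized)
contracted by a uniform per-axis factor 0.983, i.e. a ground-truth PVC of
(0.983³ − 1)·100 ≈ −5.01%:

```r
library(longivol)
fx <- end_to_end_fixture(shape_spec(), field_spec("uniform_scale"))
measure_volume_change(fx$seg, fx$field)
#> V_BL (mesh) = 2396.53 mm^3, V_FU (mesh) = 2276.38 mm^3
#> PVC mesh route     = -5.0138 %
#> PVC Jacobian route = -5.0138 % (difference -0.0000 pp)
```

Both routes recover the analytic −5.0138% (exact for affine fields), and the
baseline mesh volume is within 1% of the analytic ellipsoid volume.

Sample-size planning from published group summaries — here the group means/SDs
of a method measuring CTRL at −1.42 ± 2.650 % and AD at −4.47 ± 3.598 %:

```r
power_analysis(-1.42, 2.650, -4.47, 3.598)
#> two-group contrast: d = 0.97 (sigma_pooled = 3.160%), N = 17 per group (alpha = 0.05, power = 0.8)
```

A full simulated cohort through the whole statistics layer — exclusion beyond
±25%, left/right averaging, pooled-A/B ANOVA, reproducibility and power:

```r
tab <- simulate_cohort(cohort_spec(seed = 1))
cohort_report(tab)
#> Group summary (subject-level PVC, pooled A+B):
#>      method group      mu sigma n_obs
#> 1 simulated    AD -4.1274 4.346    40
#> 2 simulated  CTRL -0.8513 2.394    40
#> 3 simulated   MCI -2.3681 3.139    80
#>
#> Reproducibility D_Ave (A vs B, %):
#> simulated
#>     1.866
#>
#> Sample sizes:
#>      method cohen_d n_per_group n_exact contrast
#> 1 simulated   0.543          53    53.2 CTRL-MCI
#> 2 simulated   0.934          18    18.0  CTRL-AD
```

The simulated cohort (20/40/20 subjects, generating means −1.42/−2.53/−4.47 %)
recovers its group parameters within sampling error; the A-vs-B distance of
1.87% reflects the generator's 1.5% replicate noise (expectation √2·1.5 ≈
2.12% with n = 80 pairs).

A thin command-line interface wraps the same functions
(`exec/longivol simulate | extract-mesh | measure | jacobian-check | stats |
report`), reading NIfTI segmentations and fields, and writing PLY/STL meshes,
CSV record tables and JSON reports.

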