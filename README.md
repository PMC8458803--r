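# natsc

Quantitative brain sodium (²³Na) MRI estimates the absolute **Total Sodium
Concentration** (TSC, mmol/L of wet tissue) in brain structures. Altered
sodium homeostasis is a candidate early marker of neurodegeneration — in
early idiopathic Parkinson's disease the substantia nigra shows elevated TSC
before any measurable atrophy — so small patient–control studies need a
quantification chain whose every step is testable. `natsc` implements that
chain as a reusable, fully seeded pipeline on synthetic data with known
ground truth:

1. **Digital phantom + acquisition simulator** — a parametric head phantom
   (white matter, CSF, cortical gray-matter shell, five subcortical nuclei,
   six reference tubes of known concentration inside the field of view) and a
   24-echo magnitude acquisition with Rician noise and optional
   point-spread blur. Echo times follow the three staggered 8-TE
   acquisitions spanning 0.20–70.78 ms.
2. **Bi-exponential T2\* relaxometry** — per voxel, bounded nonlinear least
   squares of the two-pool decay

   S(TE) = S₀ · [ f · exp(−TE/T2\*short) + (1−f) · exp(−TE/T2\*long) ]

   recovering the ordinate at TE = 0 (S₀), the quantity proportional to
   sodium content.
3. **Phantom-tube calibration** — ordinary least squares of mean tube S₀
   against the known 25–100 mmol/L concentrations; inverting the line maps
   S₀ to absolute TSC voxelwise.
4. **ROI extraction** — mean TSC over converged voxels of each region
   (substantia nigra, putamen, caudate, pallidum, thalamus, cortical gray
   matter) and region volumes normalized by intracranial volume (% of ICV).
5. **Cohort statistics** — exact/corrected Wilcoxon rank-sum group
   comparisons, Fisher exact and chi-square tests for categorical
   demographics, Spearman correlations, and Bonferroni control across the
   six ROI comparisons (0.05 / 6 → the familiar 0.008 display threshold).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` visualisations.

## Worked example

```r
library(natsc)

spec    <- default_phantom_spec("iPD", grid_shape = c(24, 24, 24))
phantom <- build_phantom(spec)
image   <- simulate_multiecho(phantom, noise_sd = 1.5, seed = 42)
maps    <- fit_volume(image, phantom$label_volume > 0)
#> <natsc_parameter_maps> 24 x 24 x 24 grid; 4244 voxels fitted, 100.0% converged

tubes <- tibble::tibble(label_id = spec$tube_labels,
                        concentration = c(25, 40, 55, 70, 85, 100))
calib <- fit_calibration(tube_mean_signals(maps$s0_map, phantom$label_volume,
                                           tubes, maps$convergence_mask))
#> <natsc_calibration> s0 = 1.00904 * conc + -0.335286  (R^2 = 0.9998, 6 tubes)

tsc <- apply_calibration(maps$s0_map, calib, voxel_size = 3)
roi_summary(tsc, phantom$label_volume,
            icv_voxel_count = sum(phantom$label_volume %in% spec$icv_labels),
            convergence_mask = maps$convergence_mask,
            subject_id = "iPD01", group = "iPD")
#> # A tibble: 6 × 6
#>   subject_id group roi              mean_tsc voxel_count normalized_volume
#> 1 iPD01      iPD   substantia_nigra     43.0           2            0.0478
#> 2 iPD01      iPD   putamen              48.4          26            0.621
#> 3 iPD01      iPD   caudate              54.4          20            0.478
#> 4 iPD01      iPD   pallidum             45.3          11            0.263
#> 5 iPD01      iPD   thalamus             50.7          40            0.956
#> 6 iPD01      iPD   cortical_gm          56.2        1816           43.4
```

The phantom carried patient-template ground truth (substantia nigra
43.73 mmol/L, cortical gray matter 56.34 mmol/L); with noise at roughly 3%
of the tissue signal the recovered ROI means land within ~2% of truth, and
the tube calibration is linear to R² ≈ 0.9998. A cohort-level comparison:

```r
cohort <- sample_cohort(seed = 42)      # 10 patients, 12 controls
compare_groups(cohort)
#> <natsc_group_comparison> iPD vs HC; Bonferroni over 6 comparisons, threshold 0.008
#>    roi              measure mean_iPD sd_iPD mean_HC sd_HC p_uncorrected ...
#>  1 substantia_nigra tsc        48.0   3.60    36.2  5.31       0.000253
#>  3 putamen          tsc        49.4   5.15    44.7  5.60       0.0806
#>  ...
```

Only the substantia nigra TSC comparison clears the 0.008 Bonferroni
threshold in this draw — the expected behaviour for a cohort sampled from
the reference group parameters, where the substantia nigra carries the
largest standardized group difference.

The full pipeline (simulate → fit → calibrate → summarize → compare, with
NIfTI/CSV outputs and a JSON manifest) runs as one seeded call:

```r
run_pipeline(pipeline_config(master_seed = 7), out_dir = "run1")
```

or from a shell via the thin CLI in `inst/cli/natsc.R`
(`run-all | simulate | fit | quantify | stats`).

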