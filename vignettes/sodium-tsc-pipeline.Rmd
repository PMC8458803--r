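---
title: "Quantitative sodium MRI: model, simulator and statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI: model, simulator and statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natsc)
```

## The problem

Sodium (²³Na) MRI measures a signal proportional to tissue sodium content,
but raw signal units are scanner- and session-specific. Absolute
quantification therefore needs two ingredients: (i) an estimate of the signal
that *would* be measured at echo time zero, before any T2\* decay, and (ii) a
mapping from that signal to concentration, anchored by reference phantoms of
known concentration imaged in the same field of view. `natsc` implements this
chain for a small patient–control study design (10 patients with early
idiopathic Parkinson's disease, 12 healthy controls; six brain ROIs) together
with a synthetic-data generator providing exact ground truth, so that every
stage of the chain is testable end to end.

## Signal model

Sodium relaxation in tissue is bi-exponential, with a fast and a slow T2\*
pool:

$$S(TE) = S_0\left[f\,e^{-TE/T2^*_s} + (1-f)\,e^{-TE/T2^*_l}\right],$$

where $S_0$ is the ordinate at $TE = 0$ (signal units), $f \in [0,1]$ the
fast-pool signal fraction, and $T2^*_s \le T2^*_l$ (ms) the pool relaxation
times. The decay is sampled at 24 echo times between 0.20 and 70.78 ms,
obtained by merging three staggered 8-echo acquisitions
(`default_echo_schedule()`). Sampling down to 0.20 ms is what makes the
$S_0$ extrapolation well-posed: at the first echo less than 5% of even the
fast pool has decayed.

`fit_voxel()` estimates $(S_0, f, T2^*_s, T2^*_l)$ per voxel by bounded
Levenberg–Marquardt least squares (via `minpack.lm::nls.lm` with an analytic
Jacobian). Choices the data do not dictate, and how we made them:

* **Bounds** (configurable through `fit_options()`): $f \in [0,1]$,
  $T2^*_s \in [0.1, 15]$ ms, $T2^*_l \in [15, 80]$ ms, $S_0 \ge 0$. The
  15 ms split separates the pools within the sampled TE window; 80 ms caps
  the slow pool near the last echo so the tail stays informative.
* **Initialisation**: a log-linear fit of the last 8 echoes seeds the slow
  pool ($T2^*_l$ and amplitude); $T2^*_s$ starts at 4 ms and $f$ at 0.5.
  The two-pool fit is ill-conditioned, and seeding the slow pool from the
  tail keeps the optimizer out of the $T2^*_s \approx T2^*_l$ ridge.
* **Canonicalisation**: the model is symmetric under pool exchange, so
  results are reported with $T2^*_s \le T2^*_l$ (swapping pools and
  replacing $f$ by $1-f$ when needed).
* **Degenerate inputs**: an all-zero series is an exact zero-amplitude fit
  ($S_0 = 0$, converged, zero residual); mono-exponential data drive $f$
  to a bound with $S_0$ still recovered. Convergence is read from the
  optimizer's status code; voxels that hit the iteration cap are flagged
  and excluded from ROI statistics downstream.
* **Noise floor**: magnitude images carry a Rician noise floor. A
  quadrature floor subtraction
  ($\sqrt{\max(S^2 - \sigma_f^2, 0)}$, `fit_options(noise_floor = )`) is
  provided but **off by default**: at the SNR of the default simulations the
  bias it removes is smaller than the variance it adds, and at very low SNR
  the crude quadrature form can overshoot.

`fit_volume()` applies the fit across a mask. Voxels with bit-identical echo
series share one fit — the fit is a deterministic function of the series, so
this equals independent per-voxel calls while making piecewise-constant
noiseless phantoms effectively free.

## Calibration and ROI extraction

Mean fitted $S_0$ over each reference tube's converged voxels is regressed on
the known concentrations (25–100 mmol/L, six tubes, default
$\{25, 40, 55, 70, 85, 100\}$, equally spaced over the stated range). We use
a straight line with a free intercept: the intercept absorbs any residual
signal offset (e.g. noise-floor bias common to all tubes), and on noiseless
data it estimates to zero, so nothing is lost in the ideal case. A
forced-zero-intercept mode (`zero_intercept = TRUE`) is available when a pure
proportionality is preferred. Voxelwise,
$\mathrm{TSC} = (S_0 - \mathrm{intercept}) / \mathrm{slope}$; negative
calibrated values (possible under noise) are clipped to zero and counted.

ROI statistics are arithmetic means over converged voxels (a median option
exists), and region volumes are reported as percentages of the intracranial
volume, the head-size normalization under which cortical gray matter is
roughly 42–43% and the substantia nigra roughly 0.07% of ICV. No
partial-volume correction is applied — labels are nominal, matching the
crisp synthetic segmentations.

## The synthetic cohort and phantom

`sample_cohort()` draws per-subject, per-ROI ground-truth TSC and normalized
volume from group-level Gaussians truncated at zero, independently across
ROIs — the reference parameters (`roi_reference_values()`) encode the
study-design group means and SDs for both measures. Only marginal means and
SDs are modelled; real inter-ROI correlation structure is not, so passing
cohort-level tests demonstrates calibration of the marginal statistics, not
of any multivariate behaviour.

`build_phantom()` renders a parametric head: an ellipsoidal intracranial
volume (semi-axes scaled to the grid), a cortical shell whose inner radius is
derived from the target gray-matter volume fraction, a central CSF cavity,
five subcortical spheres whose radii come from the target % -of-ICV volumes,
and six tubes outside the skull but inside the field of view. Geometry is
specified in fractional grid coordinates, so the same specification scales
from the default 48³ grid (3 mm isotropic) down to the 24³ grids used in
fast tests — with the caveat that the substantia nigra renders only ~2
voxels at 24³ and ~20 at 48³, which is also the honest regime of the real
measurement (a structure near the resolution limit of sodium MRI).
Compartments that would overlap raise an error naming both labels; white
matter is a *fill* compartment claiming the remainder of its shape,
emulating carved segmentation labels.

Tissue relaxation defaults ($T2^*_s = 4$ ms, $T2^*_l = 35$ ms, $f = 0.6$;
CSF as a single slow pool; tubes sharing the tissue defaults) are generator
inputs, not claims about tissue: they put the decay squarely in the
bi-exponential regime the 0.20–70.78 ms window was designed to sample. CSF
is set to 140 mmol/L (physiological fluid sodium) and white matter to
35 mmol/L. The signal ordinate is proportional to ground-truth TSC through
one global constant (`signal_per_mmol`, default 1) shared by tissue and
tubes — the simulator assumes exact proportionality, which is precisely the
assumption the tube calibration inverts; relaxation-weighting differences
between tissue and gel are not modelled.

The acquisition simulator evaluates the decay at each echo, optionally
applies an isotropic Gaussian blur (a stand-in for the point-spread function
of the radial readout; default 0 so round-trip tests are exact), then adds
Rician noise (magnitude of complex Gaussian noise, per-channel SD
`noise_sd`). The pipeline default `noise_sd = 2` signal units is ~4% of a
typical tissue signal — SNR ≈ 25, a realistic multi-echo sodium regime.
What the generator does **not** emulate: k-space sampling, coil sensitivity,
$B_0/B_1$ inhomogeneity, motion, registration error, anatomical geometry.
Passing round-trip tests therefore validates the estimation chain, not
robustness to those effects.

In noisy round-trip tests we reference noise to the **peak brain-tissue
signal** (cortical gray matter $S_0$) rather than the image maximum: the
image maximum is CSF, whose concentration is itself a free generator
parameter, and tying a test condition to an incidental choice would make the
test measure the wrong thing. At 5% of the tissue peak, all six ROI means
recover within 2% per replicate at the 48³ grid.

## Statistical battery

The group-comparison battery reproduces a small-sample nonparametric
workflow:

* **Wilcoxon rank-sum** (`rank_sum_test()`): "Wilcoxon" is read as the
  unpaired two-sample rank-sum test — patients and controls are independent
  groups. With combined $n \le 12$ and no ties the exact null distribution
  is enumerated (all $\binom{n}{n_a}$ assignments; two-sided $p$ = twice the
  smaller tail, capped at 1); otherwise the normal approximation with
  midrank tie correction and 0.5 continuity correction.
* **Fisher exact** (`fisher_exact()`): two-sided $p$ as the sum of
  hypergeometric probabilities not exceeding the observed table's — the most
  common convention, stated explicitly because conventions differ.
* **Chi-square** (`chi2_test()`): Pearson statistic without continuity
  correction; the pipeline convention is Fisher whenever an expected count
  is below 5.
* **Spearman** (`spearman_cor()`): midranks for ties; exact permutation
  $p$ for $n \le 8$ without ties, $t$ approximation otherwise. Constant
  inputs leave $\rho$ undefined and are flagged rather than reported. No
  multiplicity correction is applied to correlation screens; all pairs are
  exported.
* **Bonferroni** (`bonferroni()`): the family is the **six TSC
  comparisons** (five subcortical ROIs + cortical gray matter), giving
  $0.05/6 \approx 0.00833$, displayed as 0.008; the exact threshold is used
  internally with strict inequality. Volume comparisons are reported
  uncorrected — the multiplicity-controlled family is the concentration
  family, volumes being a secondary atrophy screen. Whether a display
  threshold of "0.008" means the truncated or the exact value is
  undecidable from a printed table; we compare against the exact value and
  round only for display.

`compare_groups()` assembles the per-ROI × per-measure table (group means ±
SD, uncorrected $p$, family flags) from a long cohort tibble; `tidy()` and
`glance()` expose it in broom style.

## Pipeline, seeding and problem sizes

`run_pipeline()` chains the stages per subject — each subject's phantom is
re-rendered from that subject's drawn concentrations *and* volume fractions
(sphere radii and shell thickness recomputed), so measured volumes vary
across subjects and volume comparisons are non-degenerate. Every stage
writes its outputs (NIfTI volumes, CSVs, text report, JSON manifest), and
stages are individually re-runnable from saved intermediates. One master
seed drives everything; per-subject and per-stage child seeds are derived by
a deterministic string hash, so enlarging the cohort leaves earlier
subjects' data unchanged, and identical configurations produce byte-identical
CSVs.

Problem sizes used by the shipped checks (chosen as the package's own
trade-off between coverage and desk-scale runtime): fast unit and round-trip
tests run at 24³ voxels; the noiseless and noisy end-to-end recovery checks
and the reproduction script run at the full default 48³; the null-hypothesis
calibration of the comparison battery uses 500 seeded cohort replicates at
the study's 10 + 12 design.

## Known limitations

* The phantom is geometric, not anatomical; partial-volume effects exist
  only under optional blur, and no registration step is modelled.
* $S_0 \propto$ TSC is exact in simulation; in vivo, relaxation weighting
  between tissue and reference gel can bias the calibration and is not
  corrected here.
* The cohort model is marginal-Gaussian per ROI; no between-ROI or
  TSC–volume correlation is induced.
* The exact rank-sum path requires no ties; tied small samples fall back to
  the corrected normal approximation, which is conservative at very small
  $n$.
* Tube relaxation properties default to the tissue values — a simulation
  choice, flagged in the configuration, not a property of agar gel.
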