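---
title: "Methods: PET tumour volume and haematotoxicity grading with prrtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET tumour volume and haematotoxicity grading with prrtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrtox)
```

## What the package computes

`prrtox` implements the quantitative chain used to study subacute
haematotoxicity during peptide receptor radionuclide therapy (PRRT)
with [177Lu]Lu-DOTA-TATE in neuroendocrine tumour patients:

1. **Somatostatin-receptor PET tumour burden.** Focal bone and
   soft-tissue lesions are segmented at 40% of their SUVpeak; liver
   tumour volume is derived from a three-Gaussian decomposition of the
   liver SUV histogram.
2. **CTCAE v5 haematotoxicity grading.** Longitudinal haemoglobin,
   leucocyte, neutrophil and platelet series are reduced to per-patient
   and per-cycle nadir grades, patients are classed into the grade
   groups 0–1 / 2 / 3–4 by their highest observed grade, and
   treatment-course adjustments (postponed cycles, reduced activities,
   discontinuation) are flagged.
3. **Cohort statistics.** Baseline values are compared between grade
   groups (chi-square / ANOVA / Kruskal–Wallis with Bonferroni-adjusted
   post hoc tests) and baseline–nadir association is quantified by
   Pearson correlation and ordinary least squares.

Because clinical PET volumes and patient laboratory records cannot be
shipped, the package also contains seeded generators for synthetic
phantoms and cohorts with the statistical structure the downstream
stages assume. Every stage is exercised end to end on synthetic data.

## The liver method

All liver-mask voxel SUVs are binned into a fixed-width histogram
(default 0.1 SUV, from 0 to one bin past the maximum). The bin width is
a compromise: much narrower bins make counts noisy, much wider bins
blur the blood-pool component. Three scaled Gaussian densities are then
fitted to the bin counts; the components are interpreted, in
increasing-mean order, as blood pool, normal liver parenchyma and
tumour tissue. Every liver voxel with SUV strictly above
$\mu_\text{normal} + \sigma_\text{normal}$ is counted as tumour, and
the volume is the voxel count times the voxel volume.

Choices the histogram formulation leaves open, and what this package
does:

* **Fit objective.** Default is weighted least squares on the bin
  counts with weights $1/\max(c_i, 1)$ (the Poisson chi-square
  weighting), optimised by Levenberg–Marquardt. An
  expectation–maximisation fit on the binned values is available as
  `method = "em"`; both must recover a known generating mixture, and
  the test suite holds both to the same recovery tolerance.
* **Initialisation.** Deterministic: component means start at the
  histogram's 10th/50th/90th percentiles, weights equal, SDs at half
  the inter-quantile gaps. The same histogram and init always give the
  same fit; non-convergence returns the best iterate flagged
  `converged = FALSE`.
* **Component identification.** The normal-parenchyma component is the
  one with the middle mean (the ordering assumption blood pool <
  parenchyma < tumour). Exactly tied means are broken toward the larger
  weight, with a message; a manual override always wins and is recorded
  on the fit, mirroring the visual selection a physicist would perform.
* **Threshold strictness.** "Above the mean plus one SD" is read as a
  strict inequality. At floating-point resolution the choice is
  immaterial, but it is fixed so volumes are exactly reproducible.
* **Blood pool.** Blood-pool voxels inside the liver mask are *not*
  excluded before thresholding; with realistic parameters they sit far
  below the threshold.

## SUVpeak and the 40% lesion rule

SUVpeak is the maximum, over candidate sphere centres, of the mean SUV
in a 1 mL sphere: $(4/3)\pi r^3 = 1000$ mm$^3$, so $r \approx 6.2$ mm.
The discretisation is the simplest exactly testable one: candidate
centres are the voxel centres inside the operator-supplied lesion
region, and a voxel belongs to the sphere iff its centre lies within
$r$ of the candidate centre. Ties break toward the lexicographically
smallest voxel coordinate. The implementation is verified against
exhaustive brute-force enumeration (same sphere rule, same tie-break)
on dozens of random volumes — equality is exact, not approximate.

The lesion segment is the 26-connected component (configurable to 6)
of voxels at or above $0.4 \times$ SUVpeak containing the peak centre.
Two edge cases are deliberate:

* a region smaller than 1 mL still gets a sphere mean (the sphere then
  extends beyond the region) and the result is flagged
  `small_region = TRUE`;
* the sphere *mean* can exceed the centre voxel's own value, so at high
  threshold fractions the component containing the centre can be
  empty; the segment is then empty rather than an error, which keeps
  segment volume monotone in the threshold fraction.

Volumes are always voxel count × voxel volume; coordinates are 0-based
voxel indices times spacing. Automatic whole-body lesion detection is
out of scope: lesions are operator-seeded.

## The synthetic phantom

The phantom emulates the substrate the liver method assumes: a liver
ellipsoid (defaults sized to give ≈50,000 voxels at 2.5 mm isotropic
spacing) whose voxels draw from the three-component mixture, with
tumour voxels arranged as non-overlapping spherical blobs rather than
salt-and-pepper noise, so that volume accounting is meaningful. The
default component parameters are weights (0.1, 0.7, 0.2), means
(1.5, 5, 15) SUV and SDs (0.4, 1, 4) — a markedly
receptor-positive tumour on normal parenchyma with a small blood-pool
fraction. When blob radii are not supplied they are auto-sized (fixed
relative sizes) so total blob volume equals the tumour weight times
the liver volume; this is the configuration under which the empirical
histogram converges to the specified mixture. User-supplied radii are
honoured as given, and a blob that cannot fit inside the liver
ellipsoid raises an error naming it. Two extra-hepatic plateau
lesions (one "bone", one "soft tissue") sit on a 0.5 SUV background
with 0.05 SUV Gaussian noise.

What the phantom does **not** model: PET physics (point-spread
function, partial volume, attenuation, correlated reconstruction
noise) and anatomical realism. Passing tests therefore demonstrate
that the algorithms are correct on data satisfying their own
assumptions, not that the method is robust to scanner effects.

## The synthetic cohort

Patients follow the clinical schedule: up to four cycles of 7.4 GBq
every 10 weeks, blood samples at baseline and 3, 6 and 8.5 weeks after
each cycle. Baselines are drawn from the cohort's baseline
distributions — haemoglobin normal with mean 8.0 and SD 0.9 mmol/L;
leucocytes, neutrophils and platelets log-normal parameterised by
median and interquartile range (6.8 [5.6–8.0], 4.2 [3.3–5.2] and
244 [190–329] ×10⁹/L). Counts are log-normal because their reported
summaries are skewed; haemoglobin is normal because it is reported as
mean ± SD.

The post-cycle trajectory is an invented but minimal model: the value
declines linearly to `baseline × D` at a configurable nadir offset
(default 3 weeks, the first sampling offset, so the noiseless observed
nadir equals `baseline × D` exactly), then the deficit shrinks by a
fixed fraction per week (default 0.25). The decline factor for patient
*i* and cycle *c* is `clamp(mean + u_i + e_ic, 0.05, 1)` with
patient-level susceptibility `u_i` and cycle-level noise `e_ic`;
measurements carry multiplicative log-normal noise (default CV 3%) and
are floored at 0.1 unit to keep physiology positive. Default decline
means (0.95 haemoglobin, 0.70 leucocytes, 0.73 neutrophils, 0.72
platelets) were chosen once so that the typical nadir-to-baseline
ratios match the ratios clinically observed for these four parameters
in PRRT cohorts (≈0.90, 0.56, 0.60, 0.59). Susceptibility is drawn
independently per parameter, which keeps the four parameters
independent — a simplification (real cell lines share marrow
suppression) that makes the overall grade-group probabilities
factorise, so the generator can be validated against exact analytic
bin probabilities by numeric integration. Dips do not accumulate
across cycles; each cycle's decline is relative to the original
baseline.

All randomness in both generators flows from one integer seed through
`withr::with_seed()`; no global RNG state leaks in or out, and a fixed
seed reproduces volumes and cohorts bit for bit.

## CTCAE grading choices

The CTCAE v5.0 value bins ship as an editable JSON rules file
(`inst/extdata/ctcae_v5_rules.json`). Points that needed fixing:

* **Units.** Haemoglobin arrives in mmol/L (Dutch convention) and is
  converted with 1 mmol/L = 1.6113 g/dL (monomeric iron). Counts are
  ×10⁹/L throughout.
* **Lower limits of normal** default to haemoglobin 8.5 (male) / 7.5
  (female) mmol/L, leucocytes 4.0, neutrophils 1.5, platelets 150.
  Only the grade 0 vs 1 boundary depends on them.
* **Anaemia caps at grade 3** under value-based grading: CTCAE defines
  haemoglobin grade 4 clinically ("life-threatening"), not by value.
* **Bins are half-open**: a value exactly at a bound takes the milder
  grade.
* **Nadir windows.** The whole-course nadir excludes baseline records
  (day ≤ 0) but keeps them for baseline analyses; per-cycle windows
  are half-open `(cycle day, next cycle day]`, the last window running
  10 weeks past the final administration. Nadir ties resolve to the
  earliest day. Missing follow-ups are ignored (no imputation);
  observations outside every window are counted and reported, never
  silently graded.
* **Course classification describes, does not prescribe**: postponed
  means any inter-cycle interval above planned 70 days + 7 days
  tolerance; reduced means any activity below planned 7.4 GBq − 0.2
  GBq. The clinical decision rule behind such adjustments involves
  physician judgment and is out of scope.

Screening limits (haemoglobin > 5.5 mmol/L, leucocytes > 3.0,
neutrophils > 1.0, platelets > 75 ×10⁹/L, GFR > 50, albumin > 30) are
strict inequalities: a value exactly at a limit fails.

## Statistical layer

Visual normality assessment is replaced by a reproducible rule: a
variable is "normal" when its absolute sample skewness is ≤ 1,
otherwise it is log transformed if that brings the skewness inside the
band. Variables that look normal (possibly after log) are compared by
one-way ANOVA, still-skewed ones by Kruskal–Wallis, categorical ones by
Pearson chi-square without continuity correction. A significant
omnibus test (p < 0.05) triggers pairwise post hoc tests — Welch t
after ANOVA, Dunn's rank test (with tie correction) after
Kruskal–Wallis — Bonferroni-adjusted. Dunn's test is implemented in
the package because no installed dependency provides it; its z
statistics are checked against a hand computation in the tests.
Association is Pearson correlation plus OLS of nadir on baseline with
a 95% profile interval on the slope; Spearman-style robustness can be
had by log-scaling both sides (`scale = "log"` or `"auto"`).

The test suite calibrates this layer empirically: type-I error of the
omnibus tests is checked at 0.05 ± 0.015 over 1000 null simulations at
the group sizes 54/38, and the OLS interval's coverage of a true slope
0.73 at 95% ± 2% over 500 replicates.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate → segment → grade → stats, writes
every intermediate artifact (NIfTI volumes uncompressed, tables as
CSV, fits as JSON), and emits a manifest with options, seeds, package
version and an MD5 checksum per artifact. A failed stage aborts with
the stage name. Identical config and seed give byte-identical
manifests; this is asserted in the tests. The demo configuration uses
a 64³ phantom (≈50,000 liver voxels) and a 100-patient cohort — the
sizes at which the whole chain, including the statistics, runs in a
few seconds on one CPU, while the mixture-recovery and calibration
properties in the test suite use 20 phantoms and 1000-replicate null
simulations.

## Known limitations

* The phantom's Gaussian populations and plateau lesions are idealised;
  no claim is made about robustness to reconstruction artefacts,
  respiratory motion, or partial-volume bias.
* Value-based grading cannot express clinical grade criteria
  (transfusion indicated, life-threatening), so anaemia never reaches
  grade 4.
* The trajectory model has one dip per cycle and no cumulative marrow
  exhaustion; long-term toxicity (e.g. myelodysplastic syndrome) is out
  of scope.
* The synthetic cohort's baseline–nadir correlations are tighter than
  clinically observed ones because the noise model is deliberately
  simple; the statistics layer is validated by calibration properties,
  not by reproducing any particular cohort's p values.
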