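# prrtox

Quantitative tools for **peptide receptor radionuclide therapy (PRRT)**
cohorts: somatostatin-receptor PET tumour-volume segmentation and
CTCAE v5 haematotoxicity analysis, for nuclear-medicine physicists and
clinical researchers who need the whole chain — imaging burden,
longitudinal blood-count grading, and the statistics connecting them —
reproducible from a single seed.

## What it implements

**Tumour burden from PET.** Bone and soft-tissue lesions are segmented
lesion-wise at 40% of SUVpeak, where SUVpeak is the mean SUV of the
1 mL sphere ((4/3)πr³ = 1000 mm³, r ≈ 6.2 mm) with the highest average
uptake inside the lesion. Liver tumour volume uses a histogram method:
all liver-mask SUV values are binned, three Gaussian components
(blood pool, normal parenchyma, tumour; weights *wᵢ*, means *μᵢ*, SDs
*σᵢ*) are fitted to the counts, and every liver voxel with
SUV > μ_normal + σ_normal is counted as tumour. Per-compartment volumes
(bone, soft tissue, liver) sum to a total tumour load in mL.

**Haematotoxicity.** Longitudinal haemoglobin, leucocyte, neutrophil
and platelet panels are graded per CTCAE v5.0 value bins (haemoglobin
converted at 1 mmol/L = 1.6113 g/dL). Each patient gets per-parameter
nadir grades, an overall grade (the maximum across parameters), the
grade group 0–1 / 2 / 3–4 used for cohort comparisons, per-cycle
window grades, screening-eligibility checks (strict limits:
Hgb > 5.5 mmol/L, WBC > 3.0, ANC > 1.0, PLT > 75 ×10⁹/L, GFR > 50,
albumin > 30), and treatment-course flags (postponed cycles, reduced
activity, discontinuation).

**Cohort statistics.** Baseline-versus-grade-group comparisons
(chi-square / ANOVA / Kruskal–Wallis chosen by a reproducible skewness
rule, Bonferroni-adjusted Welch-t or Dunn post hoc tests) and
baseline-to-nadir Pearson correlation plus OLS regression with slope
confidence intervals.

**Synthetic data.** Seeded generators for PET phantoms (three-Gaussian
liver with spatially coherent tumour blobs, plateau extra-hepatic
lesions) and four-cycle haematology cohorts (baseline distributions,
per-cycle nadir dips, recovery, measurement noise) make every stage
testable without patient data. See the methods vignette
(`vignettes/prrtox-methods.Rmd`) for the model details and their
rationale.

## Worked example

```r
library(prrtox)

# --- imaging: phantom -> liver mixture fit -> volume report ----------
phantom <- generate_phantom(phantom_spec(seed = 42))
fit <- identify_normal_component(
  fit_three_gaussians(build_liver_histogram(phantom)))
fit
#> <mixture_fit method=wls converged=TRUE R2=0.9981>
#> # A tibble: 3 x 4
#>   component weight  mean    sd
#>       <int>  <dbl> <dbl> <dbl>
#> 1         1 0.0999  1.50 0.395
#> 2         2 0.704   5.00 1.00
#> 3         3 0.196  15.1  3.89
#> normal-parenchyma component: 2 (auto (middle mean))

liver <- liver_tumour_volume(phantom, fit)
lesions <- lapply(c("lesion_1", "lesion_2"),
                  function(nm) segment_lesion_40pct(phantom, nm, id = nm))
compile_volume_report(liver$volume_ml, lesions, c("bone", "soft tissue"))
#> # A tibble: 1 x 4
#>   bone_ml soft_tissue_ml liver_ml total_ml
#>     <dbl>          <dbl>    <dbl>    <dbl>
#> 1    3.05           5.52     240.     249.
```

The fit recovers the phantom's generating components (weights
0.1/0.7/0.2, means 1.5/5/15, SDs 0.4/1/4) to within a few percent, and
the liver volume is the mass of the mixture above
μ_normal + σ_normal ≈ 6.0 SUV.

```r
# --- haematology: cohort -> grade profiles -> association ------------
cohort <- generate_cohort(cohort_spec(n = 100, seed = 42))
profiles <- overall_patient_grade(cohort$labs)
table(profiles$grade_group)
#> 0-1   2 3-4
#>  59  37   4

tbl <- build_cohort_table(cohort$labs, profiles)
tidy(baseline_nadir_association(tbl, "baseline_haemoglobin",
                                "haemoglobin_nadir", "haemoglobin"))
#> # A tibble: 1 x 8
#>   parameter   correlation    cor_p  beta beta_low beta_high r_squared    reg_p
#>   <chr>             <dbl>    <dbl> <dbl>    <dbl>     <dbl>     <dbl>    <dbl>
#> 1 haemoglobin       0.919 1.68e-41 0.902    0.824     0.979     0.845 1.68e-41
```

59% of this synthetic cohort never exceeds grade 1, 37% peaks at
grade 2 and 4% at grade 3–4; haemoglobin nadirs track baselines
closely (r = 0.92) because the generator's noise model is deliberately
simple. `autoplot()` methods exist for histograms, mixture fits and
association fits; `plot_swimmer()` and `plot_grade_frequencies()`
render the per-cycle toxicity course.

The whole chain also runs as one reproducible pipeline:

```r
run_pipeline(default_run_config("out/", seed = 1))
```

writing every artifact (NIfTI masks, CSV tables, JSON fits) plus a
checksummed manifest, or from a shell via
`Rscript inst/cli/prrt_hemtox.R run --out out/ --seed 1`.

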