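# tumoratlas

Voxel-wise statistical mapping of tumor location against overall survival
(OS) in glioblastoma cohorts, plus the downstream survival models — for
neuro-oncology researchers who have co-registered binary tumor
segmentations (NIfTI masks on a common template grid) and a clinical
registry, and want to know *where* in the brain tumor presence is
associated with shorter or longer survival.

## What it computes

Patients are grouped by OS: short (< 6 months), medium (6–24 months),
long (> 24 months). For each pair of groups, at every voxel $v$ with
tumor counts $k_A$ of $n_A$ and $k_B$ of $n_B$:

* **tumor odds** per group, $k/(n-k)$, with the count replaced by
  $\varepsilon = 10^{-6}$ where $k = 0$ (or mirrored where $k = n$);
* **log odds ratio** $\log\!\big(\tfrac{k_A/(n_A-k_A)}{k_B/(n_B-k_B)}\big)$,
  positive where group A's tumor odds are higher;
* a **two-sided Fisher exact p-value** for the 2×2 table
  (group × tumor presence);
* a **permutation-adjusted p-value**: group labels are randomly
  reassigned (2000 times by default), whole tumors moving with their
  patients so spatial dependence is preserved, and the adjusted p is the
  proportion of null p-values below the observed one;
* a **significance mask** at adjusted p ≤ 0.01, used to mask the log-OR
  map.

Testing is restricted to voxels covered by at least `min_coverage = 10`
patients (the usual minimum-lesion-count rule in lesion-symptom mapping).

The scalar follow-up is **TVTB** — the shortest distance (cm) from the
centre of the third ventricle to the tumor border — entered into Cox
proportional-hazards models with an age × TVTB interaction, so the hazard
ratio of centrality at age $a$ is
$\mathrm{HR}_{\mathrm{TVTB}}\cdot\mathrm{HR}_{\mathrm{int}}^{\,a}$.
Binomial-logistic (biopsy-only, radiochemotherapy) and proportional-odds
(5-mL residual-tumor-volume bins) models round out the clinical stage.

A synthetic-cohort generator (`generate_cohort()` /
`generate_null_cohort()`) emits masks, registry and ground truth with the
same statistical structure, so the entire pipeline is testable without
patient data.

## Worked example

```r
library(tumoratlas)

cohort <- generate_cohort(sim_config(seed = 42))   # 215 synthetic patients
table(cohort$registry$os_group)
#>  SHORT       MEDIUM         LONG UNASSIGNABLE
#>     44          128           43            0

atlas <- run_atlas(cohort$masks, cohort$registry,
                   config = perm_config(n_perm = 500, seed = 42))
for (cmp in atlas$comparisons) print(cmp)
#> <comparison_result> MEDIUM vs SHORT (n = 172): 764 significant voxel(s)
#> <comparison_result> LONG vs MEDIUM (n = 171): 192 significant voxel(s)
#> <comparison_result> LONG vs SHORT (n = 87): 737 significant voxel(s)
```

The significant voxels concentrate in and around the generator's planted
short-survival region; `write_map(atlas$comparisons$MEDIUM_vs_SHORT$masked_log_or, "m_vs_s.nii.gz")`
exports the masked log-OR map (with a JSON provenance sidecar) for any
NIfTI viewer.

The survival stage, on a cohort whose hazard is generated from age, TVTB
and their interaction:

```r
surv_cohort <- generate_cohort(sim_config(seed = 7, survival = "exponential"))
fit_cox_os(surv_cohort$registry,
           model_spec("OS", candidate_covariates = c("age_years", "tvtb_cm")),
           screen = FALSE)
#> <OS model> n = 215
#>       term                  hr            p
#>  age_years 1.070 (1.056-1.085) 1.048337e-22
#>    tvtb_cm 0.747 (0.616-0.906) 3.110476e-03
```

Each centimetre of distance from the third ventricle lowers the hazard by
about 25% at the mean age — central tumors do worse. With the published
multivariable estimates (TVTB HR 2.406, age × TVTB HR 0.983) the
age-conditional combined effect is:

```r
published <- hazard_result_from_estimates(
  c(tvtb_cm = 2.406, "age_years:tvtb_cm" = 0.983), n_used = 206L)
round(combined_hr_tvtb(published, c(60, 80)), 2)
#> [1] 0.86 0.61
```

— centrality costs more survival in the elderly.

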