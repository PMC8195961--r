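---
title: "Statistical tumor atlas methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical tumor atlas methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumoratlas)
```

## The problem

Glioblastoma prognosis depends on where the tumor sits, not only on how
large it is. Given a cohort of binary tumor segmentation masks co-registered
to a common reference space (an MNI-like template grid) and a clinical
registry with survival, this package asks, voxel by voxel, whether tumor
presence at a location is associated with overall survival (OS), and then
follows the map-level finding with patient-level regression on a scalar
centrality metric.

The pipeline has four stages:

1. **Cohort derivation** — patients are split into short (< 6 months),
   medium (6–24 months) and long (> 24 months) OS groups; residual tumor
   volume (RTV) and its 5-mL bins are derived per the clinical rules.
2. **Atlas maps** — a tumor distribution map (patients with tumor per
   voxel), per-group tumor odds maps, and pairwise log-odds-ratio maps.
3. **Voxel-wise inference** — a Fisher exact test per voxel on the 2×2
   table (OS group × tumor presence), with a permutation-based adjustment
   that respects the spatial dependence of neighbouring voxels, and
   significance masking at adjusted p ≤ 0.01.
4. **Regression** — Cox proportional hazards for OS with an age × TVTB
   interaction, binomial logistic models for biopsy-only and
   radiochemotherapy, and a proportional-odds model on RTV bins. TVTB is
   the shortest distance from the centre of the third ventricle to the
   contrast-enhancing tumor border, in centimetres.

## OS groups and clinical derivations

Calendar months are converted to days as `round(365.25 * k / 12)`: 183 days
for 6 months, 731 for 24. Both are configurable (`os_thresholds()`). The
6–24-month group is closed on both ends (`[183, 731]`); the boundary
convention matters for day-resolution data and is asserted in the tests.
Censored patients can only be classified when follow-up exceeds 24 months;
anything shorter is `UNASSIGNABLE` and excluded from the maps with a
warning.

RTV equals the post-operative contrast-enhancing volume in resected
patients and the full preoperative volume (rim plus necrotic core) in
biopsy-only patients. RTV bins are half-open on the right — (0,5], (5,10],
(10,15], (15,20], (20,∞) — with 0 mL (gross total resection) in the first
bin, matching how interval labels like "0–5 mL" / "5.1–10 mL" are used
clinically.

## Odds maps and the epsilon substitution

For a group of size $n$ with $k$ patients having tumor at a voxel, the
tumor odds are $k/(n-k)$. Where $k = 0$ the count is replaced by
$\varepsilon = 10^{-6}$, so the odds become $\varepsilon/(n-\varepsilon)$;
where $k = n$ the mirrored substitution $(n-\varepsilon)/\varepsilon$ is
applied (and a warning logged, since the all-tumor case realistically
occurs only in small groups). Substituting the *count* — so the
"without tumor" denominator becomes $n - \varepsilon$ rather than $n$ —
keeps the log odds ratio map exactly antisymmetric under group exchange;
`epsilon_policy(denominator = "n")` switches to the plain-$n$ convention if
wanted. With $0 < k < n$ the value is $\varepsilon$-free, so the choice
only affects degenerate voxels.

## Voxel-wise inference

**Fisher exact test.** Group sizes are fixed per comparison, so the
per-voxel p-value depends only on the pair of tumor counts
$(k_A, k_B)$. `build_p_lookup()` therefore precomputes the full
$(n_A+1)\times(n_B+1)$ table of two-sided p-values (sum of hypergeometric
probabilities of tables no more probable than the observed one, with a
$10^{-7}$ relative tie tolerance so floating-point noise cannot drop
exactly-tied tables), and both the observed pass and every permutation
reduce to an O(voxels) lookup.

**Permutation adjustment.** A voxel's tumor odds are strongly correlated
with its neighbours', so per-voxel p-values cannot be interpreted
marginally. The null distribution is built by randomly reassigning the
pooled patients (with their whole tumors) to the two groups, preserving
group sizes, 2000 times by default; the adjusted p-value is the proportion
of a voxel's null p-values strictly smaller than its observed one.
Significance is adjusted p ≤ 0.01, boundary included. Labels are shuffled
between the two compared groups by default; a joint three-group shuffle is
available via `perm_config(scheme = "global")`.

Two details deserve care:

* **Ties and the strict inequality.** The literal "strictly smaller" rule
  is kept as the default. Because the per-voxel null is discrete, a voxel
  whose observed p-value equals the smallest atom of its own null gets
  adjusted p = 0 — even when that atom carries substantial probability. A
  standard add-one variant `(b+1)/(n_perm+1)` is available behind
  `perm_config(smooth = TRUE)`.
* **The analysis domain.** At thinly covered voxels the discreteness
  pathology above flags voxels at any significance level (a voxel covered
  by a single short-OS patient is flagged with probability ≈ 0.3 under the
  null). The package therefore restricts testing to voxels covered by at
  least `min_coverage = 10` patients (≈ 5% of a 215-patient cohort), the
  usual minimum-lesion-count convention in voxel-based lesion-symptom
  mapping. An exact (non-Monte-Carlo) calculation of per-voxel flag
  probabilities against coverage (see the discreteness tests) shows the
  per-voxel flag rate under the null still sits between 1% and 2% at high
  coverage — the residual anti-conservativeness of the strict rule itself —
  and the 20-replicate calibration suite bounds the realised mean flagged
  fraction at 3%. Setting
  `min_coverage = 1` restores testing of every covered voxel. Maps (counts,
  odds, log-OR) are themselves well-defined from one patient upward; the
  threshold gates only where tests are interpreted.

**Randomness.** Each comparison draws its permutations from one seed set
immediately before the permutation loop, and all per-voxel work inside a
permutation is vectorised, so results are independent of voxel traversal
order and bit-reproducible given `perm_config(seed =)`.

## The centrality metric (TVTB)

`tvtb_cm()` measures the minimum Euclidean distance, in world millimetres
divided by 10, from a reference point (supplied in world coordinates; in
the clinical application, the centre of the third ventricle) to the centre
of any border voxel of the mask — a border voxel having at least one
6-connected neighbour outside the mask or lying on the volume boundary. A
reference engulfed by the tumor scores 0; no signed interior distance is
attempted. Distances go to voxel centres, not sub-voxel surfaces: binary
masks do not justify a surface model, and the error is bounded by half the
voxel diagonal (≈ 3.5 mm at 4 mm isotropic spacing). The border is that of
the full mask (contrast-enhancing rim plus necrotic core), which shares
its outer surface with the rim in a rim-enhancing tumor.

## Regression stage

Candidate covariates are screened univariably at p ≤ 0.1; retained ones
enter the multivariable model. Interaction terms (by default only
age × TVTB, for the OS model) are tested inside the multivariable model
and kept at p ≤ 0.01 — the stricter level reflecting that many interactions
could be explored. Event-time ties use the Efron approximation (appropriate
for day-resolution data); confidence intervals are Wald on the log scale,
matching how multiplicative effects are reported clinically. Missing data
are handled complete-case per model, with exclusions recorded in the result
(patients lacking post-operative imaging have no RTV and drop from
RTV-using models only). The ordered-logistic RTV model uses resected
patients only, since biopsy-only RTV equals the preoperative volume by
construction.

With the interaction present, the hazard ratio of TVTB at age $a$ is
$\mathrm{HR}_{\mathrm{TVTB}} \cdot \mathrm{HR}_{\mathrm{age\times TVTB}}^a$
(`combined_hr_tvtb()`): with the published estimates 2.406 and 0.983 this
gives 0.86 per cm at age 60 and 0.61 at age 80 — central tumor location
costs more survival in older patients.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every
stage is testable end to end.

* **Grid and anatomy.** 32³ voxels at 4 mm, origin-centred; a brain
  ellipsoid with semi-axes (56, 60, 52) mm bounds all tumors.
* **Tumors.** Axis-aligned ellipsoids with per-axis semi-axes uniform on
  14–30 mm (median volume ≈ 40 mL, in line with the ~34 mL median and
  strong right skew of preoperative glioblastoma volumes), centres uniform
  in a (42, 46, 38) mm ellipsoid, clipped to the brain. Ellipsoids are
  deliberately simple: the mapping statistics consume only binary masks,
  and analytic shapes give known volumes and borders.
* **Planted effect.** A 4 mm sphere R at (28, 24, −14) mm. Tumors
  overlapping R are assigned SHORT OS with probability 0.6 against a 0.15
  baseline; non-SHORT patients split MEDIUM : LONG at the marginal
  122 : 41 ratio. Assignment is *balanced*: within each overlap stratum a
  random subset of exactly the planted expected size goes to SHORT, so
  every tumor has the planted marginal probability while the realised
  conditional fractions are pinned — replicate-to-replicate composition
  noise would otherwise dominate recovery experiments. R sits off-centre
  so that the analysis domain retains voxels far beyond the reach of any
  R-overlapping tumor.
* **What location coupling implies.** Any mechanism that makes central
  tumors short-surviving also *depletes* short-survivors' coverage
  peripherally — the mirror image of the central enrichment. Maps from
  such cohorts legitimately show both positive and negative log-odds-ratio
  regions; recovery tests measure sensitivity inside R and false positives
  only beyond a 40 mm dilation of it.
* **Survival.** In the default group-based mode, survival days are drawn
  uniformly within the assigned group's interval, with administrative
  follow-up 750–2924 days so censoring can only affect long survivors
  (whose OS group remains determinable). The `"exponential"` mode instead
  draws exponential survival with log-hazard linear in age, TVTB and
  age × TVTB (defaults 0.079 per year, 0.878 per cm, −0.0171) around a
  374-day baseline median — the mode used for coefficient-recovery
  experiments.
* **Covariates.** Age ~ N(65, 12²) truncated to [18, 95]; KPS ≥ 70 with an
  age-decreasing logit (~70% overall); biopsy-only probability increasing
  with centrality (~18% overall); radiochemotherapy depending on age and
  KPS (~77%); preoperative volume is the exact mask volume; resected RTV
  is a Beta-distributed fraction of it, missing with probability 0.05
  (mirroring patients without post-operative imaging).
* `generate_null_cohort()` keeps the same masks but permutes a fixed
  52/122/41 label vector independent of location — the type-I-error
  baseline.

**What the generator does not emulate:** MRI intensities, registration
error, infiltrative margins, multifocal disease, or realistic lesion shape
beyond volume. Passing recovery tests show the *statistics* behave as
designed under the assumed sampling structure, not that segmentation or
registration of real data are solved.

## Problem sizes and numerical choices

The test suites run the full pipeline at the default study conditions
(215 patients, 52/122/41 split, 32³ grid) with 500-permutation nulls for
the 20-replicate calibration suite and 2000 for single-comparison checks;
coefficient recovery uses 100 cohorts of 2000 patients. The Fisher lookup
is exact (hypergeometric sums), the permutation loop is a BLAS
matrix-vector product per permutation, and all maps are float32 on disk
(counts int16, significance uint8) with provenance in JSON sidecars.
Degenerate inputs fail loudly: empty masks, grid mismatches beyond 1e-4 mm,
constant covariates, separation in logistic fits, and fewer than two
occupied RTV bins are all errors, not silent coercions.

## Known limitations

* The strict adjusted-p rule is anti-conservative on discrete nulls even
  inside the coverage-thresholded domain (1–2% of well-covered voxels
  flagged at α = 1% under the null); the add-one variant is conservative
  but breaks the literal proportion-of-smaller definition. Both are
  exposed.
* Voxel-level inference is marginal: no cluster-extent or TFCE-style
  spatial inference is attempted.
* TVTB is resolution-limited to half a voxel diagonal and treats the mask
  border as the contrast-enhancing border.
* The proportional-odds and proportional-hazards assumptions are taken,
  not tested; only basic diagnostics (separation, convergence, constant
  covariates) are built in.
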