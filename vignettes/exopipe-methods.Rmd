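---
title: "Exosomal miRNA RT-qPCR profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exosomal miRNA RT-qPCR profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopipe)
```

# The measurement model

The package analyzes longitudinal liquid biopsies from high-risk
neuroblastoma patients: plasma exosomal miRNAs profiled on 381-assay
RT-qPCR array cards at two timepoints per patient, the onset and the end of
induction chemotherapy. The raw datum is a threshold cycle (CT): the PCR
cycle at which an assay's fluorescence crosses threshold. CT is a log2-scale
quantity — one cycle is a twofold difference in template — and *lower* CT
means *more* transcript.

Plasma exosome preparations vary widely in RNA yield, so raw CTs carry large
per-sample additive offsets (input amount, reverse-transcription efficiency).
The endogenous control conventionally used for cellular miRNA panels (U6) is
unstable in plasma, so the pipeline instead references every CT to its
sample's **global mean**: the mean CT of the assays detected in that sample,

$$\Delta CT_{sj} = CT_{sj} - \overline{CT}_{s,\ \mathrm{detected}},$$

which removes any per-sample additive offset *exactly* (a property the test
suite asserts, not merely simulates). The linear-scale relative quantity is
$RQ = 2^{-\Delta CT}$, and the treatment contrast per miRNA is the negated
delta-delta-CT,
$FC = -(\Delta CT_{\mathrm{end}} - \Delta CT_{\mathrm{onset}})$, so negative
FC means downregulation after therapy.

## Preprocessing stages and their order

The stage order is fixed and enforced by `run_pipeline()`:

1. **Reliability filter** (`filter_reliable_ct`): CTs above 32 or below 14
   are outside the instrument's reliable window and become missing. The
   window is inclusive at both bounds; *detection* (used for the global mean
   and the detection filter) is the strict condition CT < 32. The two
   boundary conventions differ at exactly CT = 32 on purpose: reliability is
   about keeping a measured value, detection about trusting presence.
2. **Global-mean normalization** (`normalize_global_mean`). A sample with
   fewer than two detected assays has no meaningful reference and aborts the
   run with a named error — sample exclusion must be an explicit decision,
   not a silent drop.
3. **Detection filter** (`detection_filter`): assays detected in fewer than
   80% of all samples (both timepoints pooled) are removed. This bounds the
   bias the imputation rule can introduce. The boundary is inclusive
   (exactly 80% is kept).
4. **Imputation** (`impute_missing`): each remaining missing value becomes
   its assay's maximum observed ΔCT plus one log2 unit — one CT cycle above
   the worst well ever recorded for that assay. An undetected well is thus
   treated as the lowest plausible expression and can never rank above an
   observed well.

The **CV diagnostic** (`cv_reduction`) quantifies what normalization
removed. CVs are compared on the linear RQ scale, where a lognormal
variable's CV depends only on its log-scale spread — so removing per-sample
offsets shows up directly as a CV drop, independent of each assay's mean
expression. (On the ΔCT scale itself, CV = sd/|mean| is dominated by how
close an assay's mean sits to zero and would not measure technical-noise
removal.) A two-sample Kolmogorov–Smirnov test compares the raw and
normalized CV distributions.

# Batch assessment (PVCA)

Samples come from several European centers, so center of origin is a
candidate batch factor. `run_pvca()` implements principal variance component
analysis: PCA on the complete ΔCT matrix, then, for each retained component,
a mixed model with every factor — origin as batch; age (binned into
tertiles), INSS stage and MYCN status as biology — and their eligible
pairwise interactions as independent random intercepts, fitted by REML with
nonnegative components (a method-of-moments one-way fallback is flagged when
the mixed model cannot be fitted). Per-PC variance proportions are averaged
with eigenvalue weights and renormalized, yielding a weighted average
proportion variance (WAPV) per factor plus a residual.

Decisions embedded here, all configurable:

* **PC retention** defaults to 60% cumulative variance, the usual screening
  convention. To *estimate* a total-variance fraction the package's own
  validation uses a 90% target instead: truncating the spectrum renormalizes
  away unstructured variance and mechanically inflates structured
  proportions (an injected 0.3 batch fraction would report near 0.5 at the
  60% target).
* **Interactions** enter only when both parents have at least two levels and
  the crossing has at least two observed cells, avoiding singular fits on
  small cohorts.
* **Verdict boundary**: WAPV(origin) strictly below 5% is negligible;
  exactly 5% is classified significant (conservative reading). The pipeline
  applies **no batch correction**; a significant verdict is a stop condition
  that requires an explicit override.
* Missing factor levels become an explicit `"NA"` stratum so no sample is
  dropped from the decomposition.

# Differential expression

`diff_expression()` reports, per miRNA, the mean ΔCT per timepoint over all
samples with data at that timepoint, RQs of those means, the fold change,
and a two-sided **paired** t-test on the per-patient end-minus-onset
difference (the samples are longitudinal; an unpaired Welch variant is
available as a configuration fallback). Assays with fewer than three
complete pairs report `NA` with a warning; an all-constant difference vector
is flagged and reported as p = 1 rather than crashing on a zero variance.
P values are Benjamini–Hochberg adjusted (`bh_adjust`, backed by
`stats::p.adjust` and cross-checked in the tests against a from-scratch
step-up implementation). `significance_filter()` keeps assays with
|log2 FC| ≥ 0.58 — log2 of a linear 1.5-fold change, applied inclusively —
and adjusted p < 0.05, recording the direction.

# Response-signature selection

`build_design()` contrasts minor responders (MR) with very good partial
responders (VGPR). Features are per-patient fold changes — the longitudinal
contrast is what separates response classes — standardized to zero mean and
unit variance with the scaling stored; constant features are dropped with a
warning. `fit_elastic_net_loocv()` fits elastic-net-penalized linear
regressions (squared-error loss on the 0/1 labels, mixing parameter 0.7) on
a grid of 100 log-spaced penalties descending four decades from the smallest
penalty that zeroes all coefficients, chooses the penalty minimizing the
leave-one-out cross-validated mean squared prediction error (ties broken
toward the sparser penalty), refits on all data, and reports the nonzero
coefficients as the signature. The regularization strength is exposed as the
penalty grid; with fourteen patients LOOCV is deterministic, so no seed is
involved.

Two properties of this estimator matter when interpreting results. First,
minimum-CV penalty selection systematically *overselects*: with a strongly
planted 3-feature signal on 14 × 81 designs the chosen model reliably
contains the planted features but typically carries several small-coefficient
noise features as well. The validation suite therefore asserts recovery as
containment of the planted signature, not exact support identity. Second,
squared-error loss on binary labels is the "minimum MSE" selection rule of
classical GLMNET usage; a logistic variant would change the path but not the
machinery.

# Chemoresistance index and survival stratification

A curated literature list (shipped as
`inst/extdata/chemoresistance_mirnas.tsv`) maps miRNAs to the six induction
drugs with the direction of modulation reported to promote resistance. For
each patient, `modulation_directions()` takes the sign of the per-patient
−ΔΔCT (no magnitude threshold by default — an exact zero has measure zero
under continuous noise — with a strict |FC| ≥ 0.58 mode available), and
`chemoresistance_index()` counts, per drug, the m listed miRNAs whose
direction matches the listed resistance direction out of M listed-and-
measured. The chemoresistance index is the add-one (Laplace) smoothed
probability

$$CI = \frac{m + 1}{M + 2} \in (0, 1),$$

which stays informative for drugs with short lists and is undefined-free at
M = 0 (such drugs — cyclophosphamide in the shipped list — are excluded from
the matrix and reported separately; their smoothed value would be an
uninformative 0.5). Listed miRNAs missing from the expression matrix are
excluded from both m and M and logged.

`kmeans_stratify()` clusters patients by Euclidean k-means on their CI
profiles (k = 2, 50 random restarts at a fixed seed; CI values already share
the (0,1) probability scale, so no re-standardization). With two clusters,
cluster 1 is relabeled to the one with the higher mean CI over carboplatin,
cisplatin and doxorubicin — the poor-responder-like profile.
`association_tests()` compares the clusters on dichotomized covariates
(INSS stage 4 vs other; MYCN amplified vs not; response MR vs PR/VGPR; EFS
event within the horizon vs event-free) with pooled two-proportion z-tests,
falling back to Fisher's exact test when the pooled proportion is degenerate.
`logrank_efs()` compares three-year event-free survival — events are
relapse, progression or death; follow-up is administratively censored at 36
months — with the standard hypergeometric-variance log-rank test.

# The synthetic cohort generator

`simulate_cohort()` draws cohorts with exactly the structure the stages
assume, plus the planted ground truth recovery tests compare against:

* per-miRNA baseline CTs uniform on [18, 30], spanning the reliable window
  with realistic censoring at the detection ceiling of 32;
* measurement noise 0.5 CT per well; a patient random intercept (0.5 CT)
  and a per-sample technical offset (1 CT), both of which global-mean
  normalization must remove;
* per-center-by-miRNA batch shifts (default sd 0.05 CT, the
  negligible-batch regime; the PVCA validation re-derives the shift sd from
  a target variance fraction);
* a +1 CT global end-timepoint shift reproducing the drop in detected
  assays after chemotherapy (it cancels out of ΔCT by construction, so it
  affects detection counts, not fold changes);
* MR-restricted signature effects on miR-29c / miR-342-3p / let-7b with
  end-timepoint CT increases 6.52 / 2.83 / 3.31 — the reported MR median
  fold-change magnitudes used as planted effect sizes;
* a single latent chemoresistance status (default prevalence 0.5, optionally
  an exactly balanced allocation for power studies) that shifts the
  carboplatin/cisplatin/doxorubicin-listed miRNAs by 1 CT in each miRNA's
  net listed direction. A single latent factor, rather than independent
  per-drug statuses, matches the two-cluster structure the stratification
  stage is designed to detect; miRNAs whose listed directions conflict
  across the three drugs receive no shift;
* exponential EFS times with base hazard 0.012/month — about a 50%
  three-year event rate, matching the cohort's relapse/death burden — a
  hazard ratio of 3 for latent-resistant patients, and independent
  exponential censoring at 0.003/month;
* an optional low-rank factor term (`cor_rank`, `cor_sd`) for miRNA–miRNA
  correlation, off by default and not validated against real card data.

What the generator does **not** emulate: exosome biology (vesicle counts,
GD2 positivity), assay-specific amplification efficiencies, plate geometry,
and realistic miRNA–miRNA correlation structure. Passing recovery tests on
these cohorts therefore demonstrates that the pipeline's inference machinery
is correct under its own model assumptions — not that those assumptions
exhaust real plasma data.

# Validation problem sizes and numerical choices

The package validates itself at deliberately modest problem sizes: PVCA
fraction recovery on 25-patient × 100-assay cohorts with balanced centers
(20 replicates per injected fraction in {0, 0.1, 0.3, 0.5}, tolerance
±0.10); elastic-net recovery on 14 × 81 designs over 50 seeds; end-to-end
chemoresistance recovery on the full 52 × 381 configuration over 50 seeds;
oracle equivalence (BH step-up, sign-flip permutation t, observed-minus-
expected log-rank, soft-threshold lasso on orthonormal designs) on small
random instances; and global-null calibration over 200–1000 replicates.

Numerical conventions worth knowing: the elastic-net convergence threshold
is tightened to 1e-10 so penalty-limit comparisons against closed forms are
meaningful; REML variance components are clamped at zero and a
method-of-moments fallback is flagged per principal component; k-means
restarts and the latent-state draws restore the caller's RNG state; ties in
LOOCV MSE resolve to the sparser model; and exact-zero fold changes count as
"none" (not concordant) in direction calls.

Known limitations: with only four center levels, REML estimates of the
origin component on a single PC are noisy, and WAPV on very small matrices
(a dozen patients) can fluctuate by several percentage points around the 5%
verdict boundary; the log-rank comparison of CI clusters at a hazard ratio
of 3 in a 52-patient cohort with ~28 expected events has asymptotic power of
only ~0.8 even with perfect cluster recovery, so non-significant survival
splits in cohorts of this size are expected in a material fraction of runs
and are not evidence against the index itself.
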