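# exopipe

Analysis pipeline for **longitudinal exosomal miRNA profiles** measured by
RT-qPCR array cards in liquid biopsies of high-risk neuroblastoma patients.
Plasma exosomes are profiled at two timepoints — tumor onset and the end of
induction chemotherapy — on 381-assay cards, and the package turns the raw
threshold cycles (CT) into response signatures, a per-patient per-drug
chemoresistance probability, and a survival stratification.

## The model in brief

CT is log2-scale: one PCR cycle is a twofold template difference, and lower
CT means more transcript. The pipeline:

1. **CT reliability filter** — CTs outside [14, 32] become missing.
2. **Global-mean ΔCT normalization** — ΔCT = CT − mean(detected CTs of the
   sample), with detection defined as CT < 32. This removes per-sample
   additive technical offsets exactly; RQ = 2^(−ΔCT) is the linear-scale
   relative quantity. A Kolmogorov–Smirnov test on linear-scale coefficients
   of variation quantifies the removed technical noise.
3. **Detection filter and imputation** — assays detected in ≥ 80% of samples
   are kept; remaining missing wells are set to the assay's worst observed
   ΔCT + 1 log2 unit (one cycle above its highest recorded CT).
4. **PVCA batch verdict** — principal variance component analysis
   decomposes expression variance over center of origin (batch), age, INSS
   stage and MYCN status via per-PC REML mixed models; a weighted average
   proportion variance (WAPV) of the batch factor below 5% is negligible.
   No batch correction is applied; a significant verdict halts the run
   unless overridden.
5. **Differential expression** — paired t-tests on per-patient
   ΔCT(end) − ΔCT(onset), Benjamini–Hochberg adjustment, and the
   significance rule |log2 FC| ≥ 0.58 (linear 1.5-fold) with adjusted
   p < 0.05, where FC = −ΔΔCT (negative = downregulated after therapy).
6. **Elastic-net signature** — leave-one-out cross-validated elastic net
   (mixing 0.7, squared-error loss) on per-patient fold changes contrasts
   minor responders (MR) with very good partial responders (VGPR).
7. **Chemoresistance index** — for each patient and induction drug, the
   add-one-smoothed fraction of literature-listed miRNAs modulated in the
   resistance-associated direction: **CI = (m + 1) / (M + 2)**, a
   probability in (0, 1).
8. **Stratification and survival** — k-means (k = 2) on the patient × drug
   CI matrix, cluster association tests (two-proportion z), and a
   three-year event-free-survival log-rank comparison.

A synthetic-cohort generator (`simulate_cohort()`) with planted ground truth
— batch fractions, response signatures, latent chemoresistance, EFS hazard
ratios — makes every stage testable end to end without any patient data.

## Worked example

```r
library(exopipe)

cfg    <- sim_config(seed = 7)          # 52 patients, 381 assays, 2 timepoints
cohort <- simulate_cohort(cfg)
cohort$ct
#> ct_matrix: 381 miRNAs x 104 samples (52 onset, 52 end), 619 missing wells

chemo <- read_chemoresistance_list(packaged_chemoresistance_path())
res   <- run_pipeline(cohort$ct, cohort$clinical, chemo)
res
#> pipeline_result
#>   assays kept: 381, significant: 2
#>   batch verdict: negligible (WAPV 0.025)
#>   signature: hsa-miR-342-3p, hsa-miR-26a, hsa-miR-17, hsa-let-7b, hsa-miR-29c, ...
#>   clusters: 25/27; log-rank p = 5.533e-05

res$survival
#> log-rank chisq = 16.256 (df 1), p = 5.533e-05
#>  cluster  n events
#>        1 25     15
#>        2 27      3
```

Reading the output: the batch WAPV (2.5%) is under the 5% ceiling, so no
correction is needed; the elastic net recovers the three planted signature
miRNAs (miR-29c, miR-342-3p, let-7b) among its selections; and k-means on
the chemoresistance index splits the cohort into a poor-responder-like
cluster 1 (high CI toward carboplatin/cisplatin/doxorubicin, 15/25 events by
three years) and a good-responder cluster 2 (3/27 events), a split the
log-rank test calls at p ≈ 6e−5 because this cohort was generated with a
hazard ratio of 3 for its latent-resistant patients.

The packaged reference tables can be analyzed directly:

```r
summarize_list_by_drug(chemo)[1:3, ]
#>          drug n_up n_down
#> 1   cisplatin   19      7
#> 2   etoposide    1      5
#> 3 doxorubicin   10      6

nrow(significance_filter(published_diffexpr_summary()))
#> [1] 62
```

## Vignette

`vignettes/exopipe-methods.Rmd` documents the measurement model, every
tunable threshold with its default and rationale, the synthetic generator's
assumptions and limits, and the package's numerical conventions.
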