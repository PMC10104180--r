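# eznorm

Normative abnormality mapping of structural connectivity and interictal
iEEG for epileptogenic-tissue localisation.

## What this package is for

When people with drug-refractory focal epilepsy are evaluated for
resective surgery, two routinely acquired but under-used data types carry
localising information: diffusion-MRI structural connectomes (fractional
anisotropy, FA, per region pair) and interictal intracranial EEG (iEEG)
band power. `eznorm` quantifies how abnormal each brain region is in each
modality relative to normative references, and asks whether the surgery
removed the most abnormal tissue — a question whose answer predicts
post-surgical seizure freedom.

For a patient *j*, connection abnormality is the z-score
*A<sub>ij</sub>* = (*C<sub>ij</sub>* − *μ<sub>i</sub>*)/*σ<sub>i</sub>*
against healthy-control connection statistics (after ComBat-style site
harmonisation and robust age/sex correction), summarised per region as
*R<sub>kj</sub>* = mean of *A<sub>ij</sub>* over the region's
connections, with larger reported scores meaning greater FA reduction.
iEEG abnormality z-scores each region's relative band power (five
canonical bands, log10-transformed, normalised to sum to 1 per contact)
against a normative band map and takes
*B<sub>kj</sub>* = max<sub>f</sub> |*z<sub>fkj</sub>*|. The link to
surgery is the distinguishability statistic

> *D<sub>RS</sub>* = normalised Mann-Whitney U between resected and
> spared regional abnormalities ∈ [0, 1],

where 0 means the largest abnormalities were all resected. Cohort-level
machinery includes per-patient linear-SVM separability of resected vs
spared abnormalities (with the maximal-abnormality-resected call),
Yates-corrected chi-squared tests and Woolf-interval odds ratios, ROC
AUCs of D_RS against outcome, a depth-two decision tree constrained to
one cut per modality, and leave-one-out cross-validation.

A synthetic-cohort generator (`cohort_config()`, `generate_cohort()`)
plants epileptogenic effects — FA reductions on EZ-incident connections,
band-power shifts at EZ contacts, partial electrode coverage, resections
that noisily cover the EZ — so the whole pipeline is testable end to end
without any patient data. See the methods vignette
(`vignettes/methods.Rmd`) for the models, parameter defaults and design
choices.

## Worked example

```r
library(eznorm)

cfg <- cohort_config(n_controls = 24, n_patients = 10, n_regions = 40,
                     n_ieeg_normative = 10, seed = 7)
cohort <- generate_cohort(cfg)
res <- analyse_cohort(cohort)

head(res$patients[, c("id", "drs_conn", "drs_ieeg", "separable",
                      "maximal_resected", "good_outcome")], 5)
#>       id  drs_conn  drs_ieeg separable maximal_resected good_outcome
#> 1 pat001 0.2549020 0.3333333     FALSE               NA         TRUE
#> 2 pat002 0.3872549 0.2857143      TRUE             TRUE         TRUE
#> 3 pat003 0.4264706 0.3333333     FALSE               NA         TRUE
#> 4 pat004 0.2500000 0.0000000      TRUE             TRUE         TRUE
#> 5 pat005 0.3823529 0.1875000     FALSE               NA         TRUE

res$cohort$auc_conn$auc   # 0.571  — P(D_RS poor > D_RS good), connectivity
res$cohort$auc_ieeg$auc   # 0.833  — same for iEEG
print(res$cohort$tree)
#> <constrained_tree> root: ieeg <= 0.4167; second cut (low child):
#>   conn <= 0.5147; training accuracy 0.900 (9/10)
```

Per patient: `drs_conn`/`drs_ieeg` near 0 mean the most abnormal regions
were resected (favourable); `maximal_resected` says whether the corner of
maximal joint abnormality fell in the SVM's resected zone. At cohort
level the AUCs measure how well each modality's D_RS separates good from
poor outcomes, and the constrained tree classifies outcomes from both
D_RS values with one cut per modality.

The same analysis runs from files: `write_cohort()` emits connectivity
TSVs, contacts TSVs, flat-binary recordings with JSON sidecars, NIfTI
parcellation/masks and a manifest CSV; `run_pipeline()` orchestrates
ingest → abnormality maps → resection labeling (strict >10% volume-loss
rule by default) → statistics, writing per-patient results, a cohort
report JSON and a provenance record, reproducibly for a fixed
configuration.

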