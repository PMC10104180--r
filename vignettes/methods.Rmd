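---
title: "Normative abnormality mapping for epileptogenic-tissue localisation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative abnormality mapping for epileptogenic-tissue localisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eznorm)
```

## The problem

In drug-refractory focal epilepsy, resective surgery succeeds when the
epileptogenic zone (EZ) — the tissue whose removal is necessary and
sufficient for seizure freedom — is correctly localised and removed.
`eznorm` implements a two-modality, fully quantitative localisation
analysis: structural connectivity abnormalities from diffusion MRI
(fractional anisotropy, FA) and functional abnormalities from interictal
intracranial EEG (iEEG) band power. Both are expressed as z-scores
against normative references, summarised per parcellation region, and
related to the surgical resection and the post-surgical outcome (ILAE
class, dichotomised as good = 1–2, poor = 3+).

## Connectivity abnormality model

Each subject contributes a symmetric region-by-region FA-weighted
connectivity matrix on a fixed parcellation (128 regions by default),
with a shared presence scaffold: a connection either exists for the whole
cohort or not at all. The normative pipeline has a fixed stage order, and
tests guard against silent reordering:

1. **Site harmonisation.** A ComBat-style per-connection location/scale
   batch model with age and sex protected as covariates. By default the
   batch parameters are used unshrunk (`shrinkage = "none"`), so the
   empirical between-site difference of every connection is removed
   exactly; `shrinkage = "eb"` applies classic parametric empirical-Bayes
   shrinkage (via `sva::ComBat`). We default to the unshrunk estimator
   because the pipeline's contract is that a planted site offset must be
   removed below the z-scoring noise floor: EB shrinkage by design leaves
   a shrunken fraction of each connection's apparent batch difference in
   place (roughly half at 40 subjects per site), which propagates a
   site signature into downstream z-scores. With dozens of subjects per
   site the per-connection estimates are stable enough not to need
   shrinkage. Patients are harmonised jointly with controls by default
   (`joint = TRUE`), since both cohorts are scanned at the same sites; a
   controls-only mode is available.
2. **Covariate correction.** Per connection, a robust linear model
   (Huber M-estimation, tuning constant 1.345, IRLS to relative
   coefficient change < 1e-6 or 50 iterations; OLS fallback on
   non-convergence, counted and warned) of weight on centred age
   (reference 30 years) and sex, fitted on healthy controls only. The
   control-fitted coefficients are applied unchanged to patients, so a
   patient's abnormality is never absorbed into the covariate fit.
3. **z-scoring.** Per connection, the normative mean and sample SD
   (denominator n−1) over corrected control weights give
   A = (C − μ)/σ for each present connection of a patient. Connections
   with σ < 1e-8 are flagged unusable, never silently dropped.
4. **Regional summary.** A region's abnormality is the mean of A over its
   incident connections. The default sign convention (`"reduction"`)
   reports the *negated* mean z, so that larger scores mean greater FA
   reduction — FA reductions, not increases, are the expected white-matter
   signature in epilepsy. `"raw"` and `"absolute"` modes are available
   and recorded in the profile.

A held-out control z-scored against such a model has mean ≈ 0 and SD
slightly above 1 (≈ 1.05–1.15): the per-connection covariate coefficients
are estimated from finite controls, and the held-out subject's leverage
(age far from the control mean) inflates prediction variance. This is
expected behaviour of normative models fitted at realistic cohort sizes,
and the packaged tests assert exactly this calibration window.

## iEEG abnormality model

Seventy seconds of awake interictal recording per patient are analysed:

- **Referencing.** Common average reference (idempotent; undefined for a
  single contact).
- **Spectral estimation.** Welch PSD with 2 s Hamming windows and 50%
  overlap, mean-averaged. Two-second windows give 0.5 Hz resolution, the
  coarsest grid that still resolves the 1 Hz lower delta edge inside a
  70 s window.
- **Band power.** Trapezoidal integration over the five canonical bands
  (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–80 Hz). Band
  edges are half-open `[low, high)` so shared edges are counted once.
- **Relative band power.** Band powers are log10-transformed then
  normalised to sum to 1 per contact. The literal log-then-normalise
  order is only well defined when every raw band power exceeds 1 in its
  native units, so a positivity guard rejects smaller values with an
  instruction to rescale; a `"normalize-then-log"` alternative is
  provided for data where the guard cannot be met. The two orders give
  different numbers; the choice is recorded in the run parameters.
- **Regional assignment.** Each contact is assigned to the closest grey
  matter region within 5 mm (Euclidean distance to the nearest voxel
  centre; ties broken by lowest region id); farther contacts are left
  unassigned. Regional relative band power is the mean over assigned
  contacts.
- **Normative z-scoring.** A normative band map stores the mean and
  sample SD of regional relative band power per (region, band) across a
  designated normative subject set, with cells flagged unusable below 5
  subjects or SD < 1e-8. A patient region's abnormality is
  B = max over bands of |z|; regions with fewer than 3 usable bands are
  excluded so the max-abs summary stays meaningful.

## Resection labeling

Given a parcellation volume and a binary resection mask in pre-operative
voxel space, a region is resected when the fraction of its voxels inside
the mask strictly exceeds the threshold — 0.10 by default (>10% regional
volume loss), with 0.25 and 0.50 as the usual robustness settings and
arbitrary values allowed. The strict inequality is deliberate and tested
at the boundary (exactly 10 of 100 voxels masked is spared at 0.10).
Registration of post- to pre-operative imaging is upstream of this
package: the mask must already live in pre-operative space.

## Localisation statistics

- **D_RS** — distinguishability of resected from spared tissue: the
  normalised Mann-Whitney U over regional abnormality scores, i.e. the
  probability that a random spared region out-scores a random resected
  one (ties 1/2). 0 means the largest abnormalities were all resected.
  Connectivity D_RS uses all regions; iEEG D_RS only implanted regions.
  The implementation is rank-based and is cross-checked in tests against
  an explicit pair-counting loop and against `wilcox.test`'s U.
- **SVM separability.** Per patient, a linear-kernel SVM (fixed penalty
  C = 1e4, unscaled features) is fitted to the implanted regions'
  (iEEG B, connectivity score) points labelled resected/spared. The
  patient is *separable* when the trained classifier makes zero training
  errors — with a near-hard-margin penalty this coincides with linear
  separability on these small point sets. The *maximal abnormality*
  point is the componentwise maximum over the patient's observed
  abnormalities; `maximal_resected` records the zone that corner falls
  in. Patients with fewer than two regions in either class are "not
  evaluable", distinct from "not separable".
- **Association and discrimination.** The maximal-resected-by-outcome
  2×2 table is tested with Pearson chi-squared with Yates continuity
  correction (the base-R default for 2×2 tables) and summarised by the
  odds ratio with a Woolf interval, exp(log OR ± z·√Σ1/cell) at
  z = qnorm(0.975); any zero cell triggers the Haldane–Anscombe +0.5
  correction, flagged in the result. Outcome discrimination of D_RS is
  the ROC AUC oriented so that higher D_RS predicts poor outcome, with a
  two-sided Mann-Whitney p-value.
- **Constrained decision tree.** Outcome classification from the two
  D_RS values uses a depth-two tree constrained to exactly one cut per
  modality: a root cut on one modality, a second cut on the other inside
  one root child, the remaining child a leaf. All cut placements
  (midpoints between consecutive sorted unique values), both root
  modalities and both child positions are searched exhaustively; leaves
  take their training majority class (ties labelled seizure-free).
  Ties in training accuracy are broken deterministically: larger minimum
  margin at the chosen cuts, then an iEEG root, then lower thresholds —
  so reruns are bit-identical. Leave-one-out cross-validation refits the
  full search per fold; *sensitivity* refers to the seizure-free class
  and *specificity* to the poor-outcome class (the convention is
  recorded in the output). Folds whose training labels collapse to one
  class predict that class and are flagged.
- **Modality correlation.** Pearson (default) or Spearman correlation of
  paired abnormalities or paired D_RS values, with two-sided p.

## The synthetic cohort: what it emulates and what it does not

No patient data ship with the package; every downstream stage is
exercised on synthetic cohorts with planted effects
(`cohort_config()` → `generate_cohort()`).

Defaults mirror a two-site study of 96 healthy controls and 43 surgical
patients on a 128-region parcellation. Ages are Uniform(18, 65) with
reference age 30; sexes are balanced within site. Connection weights
follow per-connection baselines (Normal(0.45, 0.05), clipped) plus an
age slope (−0.001 FA/year), a small female offset (0.01), per-site
additive offsets (0.03) and noise-scale multipliers (1.25), and
subject noise of SD 0.04 FA — magnitudes chosen to be plausible for
tract-averaged FA, since per-connection FA distributions are not
published; all are user-configurable. Patients carry planted EZ regions:
every EZ-incident connection is lowered by `ez_fa_reduction` (default
2.5) times the noise SD, and EZ electrode contacts receive a log10
band-power shift (default +1 in the delta band, emulating pathological
slowing). Recordings are 1/f²-coloured noise with a white floor,
synthesised in the frequency domain so the planted shift moves the
expected log10 band power by exactly the requested amount; 70 s at
256 Hz by default (a standard clinical rate with >3× margin over the
80 Hz gamma edge).

Implantations cover a quarter of the regions, include each EZ region
with probability 0.9, and always sample at least two to-be-resected and
two spared regions (resections are planned from the implantation, so
this mirrors clinical reality). Resections cover the full EZ with
probability 0.6; outcomes are good if and only if the EZ was fully
resected, then flipped with probability 0.1 — giving an expected
seizure-freedom rate of 0.6·0.9 + 0.4·0.1 = 0.58. Critically, outcomes
are generated *only* from EZ coverage, never from abnormality scores, so
recovery of outcome structure by D_RS and the decision tree is a genuine
test rather than a circular one. The normative iEEG set emulates a
pooled normative map: designated subjects with full regional coverage
and unshifted spectra.

The generator does **not** simulate raw diffusion images, tractography,
seizures, interictal spikes, electrode geometry along shafts, or
artefacts. Passing tests therefore demonstrate that the pipeline's
statistical machinery recovers planted effects under its own model
assumptions — not that the method works on real recordings.

## Numerical choices and degenerate inputs

- Sample SDs use n−1 throughout; σ or map cells below 1e-8 are flagged
  unusable rather than dropped.
- Band integration uses the trapezoid rule on the 0.5 Hz Welch grid.
- Seeds: every generator takes an explicit seed; cohort stages derive
  child seeds deterministically from the master seed, and generation
  restores the caller's RNG state. Identical configurations are
  bit-identical end to end.
- Degenerate statistics inputs fail loudly and specifically: empty
  resected or spared class, zero-margin 2×2 tables, single-contact CAR,
  zero-variance correlation inputs. Single-class tree inputs return a
  trivial perfect tree with a warning.
- Tests exercise the pipeline at reduced problem sizes (20–45 regions,
  16–96 controls, 6–40 patients, 20 replicate cohorts for the recovery
  properties) chosen to keep the full suite comfortably reproducible on
  a laptop while leaving the statistical contrasts unambiguous.

## Known limitations

- The harmonisation default removes empirical site differences exactly;
  when site and a biological variable of interest are confounded, this
  removes the biology too. The generator deliberately decouples sex from
  site for this reason.
- The log-then-normalise relative band power is undefined for band
  powers ≤ 1; the guard surfaces this rather than silently switching
  conventions.
- `maximal_resected` depends on the SVM boundary only through the
  componentwise-maximum corner, which may lie far outside the observed
  point cloud for discordant modalities.
- LOOCV of an exhaustively searched tree is optimistically biased at
  very small n when margins are tiny; the per-fold refit at least avoids
  threshold leakage.
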