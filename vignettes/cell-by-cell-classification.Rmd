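---
title: "Probabilistic cell-by-cell classification of prostate tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic cell-by-cell classification of prostate tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclass)
```

## The problem and the modeling idea

Histopathological review of prostate needle biopsies misses higher-grade
disease in a substantial fraction of patients, because a biopsy samples a
small part of the gland and the readout is tissue morphology. Epigenetic
aberrations — global loss of DNA methylation (5mC) and hydroxymethylation
(5hmC) — appear early in prostate carcinogenesis and can extend into
histologically benign tissue near a tumor (field cancerization). 3D
high-content imaging of immunofluorescently labeled nuclei turns those
aberrations into *per-cell* measurements: for every segmented nucleus, the
integrated intensity of each marker channel (DAPI for DNA content, AMACR,
5mC, 5hmC) on a 12-bit scale.

This package implements the statistical half of that workflow as a tested
pipeline. A tissue is not scored as one unit; instead every imaged cell is
classified, and the tissue-level call is assembled from the cell
composition:

1. **Exploration** — compartment-stratified PCA of the log intensities to
   find where the marker panel covaries with diagnosis.
2. **Binary scoring** — a logistic model assigns each cell a probability
   of being cancerous; an operating cutoff turns probabilities into
   normal/aberrant calls; a cutoff scan and ROC/AUC banding quantify the
   operating characteristics.
3. **Staging/grading** — a k-nearest-neighbor classifier under Mahalanobis
   distance assigns each cell a pathological category (benign, ASAP, AC,
   LAC, stage II, stage III) or a Gleason group (benign, 3+3, 3+4, 4+3).
4. **Aggregation** — the fuzzy-logic largest-share rule converts per-cell
   calls into a specimen-level probabilistic diagnosis: 80% normal cells
   means an 80% probability the tissue is normal.

No raw per-cell imaging data are publicly deposited for this design, so
the package ships a synthetic-cohort generator as a first-class, tested
module, and all quantitative claims in the test suite are made either
about internally recomputable published numbers or about synthetic
cohorts with known truth.

## The synthetic cohort generator

**Generative family.** Channel intensities in tissue are strongly
right-skewed, and the original analysis log-transformed every channel
before modeling. The generator therefore draws, for each (pathological
class, compartment) stratum, log intensities from a multivariate normal —
i.e. intensities are multivariate log-normal — parameterized by a
`class_profile` (log-mean vector, log-covariance, expected cell share).
Intensities are exponentiated and clipped to the 12-bit ceiling (4095);
cells with any clipped channel are flagged.

**Default geometry.** The benign epithelial baseline uses log-means
`(DAPI 6.40, AMACR 5.20, 5mC 6.10, 5hmC 5.90)` — geometric means of a few
hundred intensity units on the 12-bit scale — with log-scale standard
deviations 0.35–0.55 and modest positive correlations (0.5 between the
two cytosine marks, 0.1–0.2 elsewhere). The full-strength aberrant effect
is `(+0.45, +0.35, −0.90, −0.70)` in log units: DNA content and AMACR up,
both epigenetic marks down, matching the observed direction of each
marker in adenocarcinoma versus benign tissue. Effect magnitudes are
package choices — the original work prints no per-class means — and are
deliberately *not* presented as measured values. Severity scales the
effect monotonically (ASAP 0.35, AC 1.0, LAC 1.25, stage II 1.5, stage
III 1.75), and the compartment attenuates it (E 1.0, E+s 0.7, ES 0.4,
S 0.0): the pure stromal compartment carries no class signal, reflecting
the finding that stroma by itself showed no significant marker
covariation.

**Cohort structure.** Five patients, biopsy plus prostatectomy, frames
split 40/30/20/10% across E/E+s/ES/S. Each specimen has its own
diagnosis-dominated class mixture: one benign biopsy acts as the healthy
control (92% benign cells), the other biopsies are dominated by
LAC/ASAP-spectrum cells and the prostatectomies by stage II/III cells,
each with a 15–25% benign admixture. The default size (1,500 cells per
specimen, 15,000 total) is a deliberate scale-down of the ~139,165-cell
development database; every count is configurable, and the k-NN
subsampling test exercises the full 139,165-cell size. A `culture`
configuration mimics the two validation cell types (a normal primary
epithelial culture and an adenocarcinoma line) with missing compartment.

**What the generator does not emulate.** Spatial structure within frames,
segmentation artifacts, batch/acquisition drift between specimens,
within-patient correlation beyond the specimen mixtures, and the
open question of whether correlated channels should reproduce the
published sign flip of AMACR (marginally up in cancer, multivariate odds
ratio below 1) — the default covariance is class-independent and the flip
is not forced, though users can encode it via `class_profile`
covariances. Passing tests on this generator therefore demonstrate
*algorithmic correctness under the stated assumptions*, not clinical
performance on real tissue.

## Per-cell data model and transforms

A `cell_table` is a data frame with identity columns, closed-vocabulary
annotations (compartment E/E+s/ES/S, pathological category, Gleason
group), and one nonnegative intensity column per marker. The CSV dialect
is UTF-8, comma-separated, "." decimals, with a JSON provenance sidecar;
doubles are written with 17 significant digits so a write/read round
trip is value-exact.

`log_transform()` replaces `v` by `ln(max(v, floor))`. The original work
is silent on zero-valued intensities; dropping such cells would distort
the composition counts that the tissue-level diagnosis depends on, so the
package clamps to a configurable positive floor (default 1 intensity
unit) and flags the affected cells. Cells are labeled for the binary
model by tissue of origin — every cell from non-benign tissue counts as
aberrant — because no per-cell ground truth exists; this is the same
assumption the original design makes, and its main cost (label noise in
benign-adjacent tissue) is discussed there as field cancerization.

## PCA choices

PCA is computed by eigendecomposition of the sample correlation matrix
(markers ≤ 5, so no truncated solver is needed). Standardization is the
default because the channels sit on different intensity scales; the
original text does not state its choice, and qualitative loading claims
can depend on it — the package exposes `standardize = FALSE` for
covariance-matrix PCA. Components are sign-fixed (largest-magnitude
loading positive) for run-to-run determinism; eigenvalue ties inherit the
stable marker order.

## Logistic stage

The binary model is ordinary maximum-likelihood logistic regression,
fitted by IRLS with convergence at max |score| < 1e-8 or relative
log-likelihood change < 1e-10; the coefficient covariance is the inverse
observed information. Separation is surfaced as an error rather than
silently ridge-regularized, keeping estimates comparable with
conventional odds-ratio reporting. Coefficients are reported delta-method
style: OR = exp(β), SE(OR) = OR·SE(β), z = β/SE(β), 95% CI =
exp(β ± 1.959964·SE(β)); the same arithmetic runs backwards from a
printed (OR, SE) pair, which is how the test suite verifies the published
coefficient tables are internally consistent.

The cutoff scan evaluates sensitivity/specificity at cutoffs 0 to 1 in
steps of 0.05 (21 rows; a cell is called aberrant when its probability is
at least the cutoff). The published operating cutoffs are shipped as
presets (0.75 for the epithelial-only model, 0.9 for the all-cells
model); whether those were chosen by the Youden rule or by inspection is
not stated, so the generic mechanism here is the scan plus the Youden
index, ties resolved toward the smaller cutoff. AUC is computed as the
Mann-Whitney concordance probability with ties counted 1/2, and is
interpreted with the Hosmer-Lemeshow bands (none at 0.5, acceptable
above 0.7, excellent above 0.8, outstanding above 0.9); the band for
(0.5, 0.7] is labeled "poor" as a documented extension, since the quoted
rules do not cover it.

## k-NN stage

The multiclass stage is k-NN (k = 5, the value reported to work best)
under Mahalanobis distance, with the metric defined by the inverse
*pooled* covariance of the reference log-intensities — the original text
says only "Mahalanobis distance", and a single pooled metric is the
standard reading; a per-class metric would change the classifier into
something closer to QDA. The reference is capped at 30,000 cells
(reported as the optimal portable reference size), drawn proportionally
by class with largest-remainder rounding under a fixed seed. Neighbor
search is an exhaustive scan (at most 30,000 references in ≤ 5
dimensions), implemented as Euclidean search after whitening by the
Cholesky factor of the inverse covariance; distance ties break by
reference index for reproducibility.

The original analysis reports that ~4% of cells could not be classified,
without defining the failure mode; here the failure mode is made precise:
a tie in the plurality vote yields `ABSTAIN`. Abstained cells are
excluded from accuracy and from composition denominators but always
reported — the published convention of quoting accuracy "from the
remaining 96% of cells" is mirrored by quoting accuracy over classified
cells with the abstain rate alongside. With heavily overlapping synthetic
classes the tie rate is considerably higher than 4%; it drops toward zero
as class separation grows and is exactly zero at k = 1.

## Aggregation

`compose()` turns per-cell calls into class fractions over classified
cells; `majority_diagnosis()` reads the largest share as the probability
of that specimen-level diagnosis. Exact ties — which the original
analysis never encounters or defines — resolve toward the more severe
class (B < ASAP < AC < LAC < StageII < StageIII; B < G33 < G34 < G43),
a conservative-toward-malignancy choice that is always flagged in the
output. Display rounding is half-away-from-zero at two decimals; the
published tables contain at least one cell inconsistent between
truncation and rounding (10,775/17,437 prints as 61.79 where rounding
gives 61.80), so the package documents its own convention and keeps
full-precision fractions in machine output rather than chasing
table-exact reproduction of that cell. A deterministic
aberrant-fraction threshold for a hard malignancy call is deliberately
out of scope (the original work defers it); the fraction itself is the
result.

## Pipeline, seeds, and problem sizes

`run_pipeline()` chains the stages and returns one report; the global
seed is expanded into per-stage seeds by a fixed counter scheme
(`stage_seed()`), so any stage can be rerun in isolation. Reruns with the
same configuration are identical.

The suite and the acceptance script use sizes chosen to keep the whole
analysis at desk scale while leaving the statistical assertions sharp:
50,000 cells for closed-form/SE convergence and coefficient-recovery
checks (10 seeds), 100 thirty-cell instances for exact AUC-vs-concordance
equivalence, 500 queries against 2,000 references for k-NN brute-force
equivalence, 20 end-to-end runs of a 3,000-cell null cohort for the
chance-level control, and a 139,165-cell cohort once, for the
subsampling contract. The null control uses identical profiles *and*
equal class shares, under which the mean training AUC stays within
0.5 ± 0.05 (the small upward excess is in-sample optimism of a
4-predictor fit, visible because evaluation is on the development data,
as in the original design).

## Known limitations

- Standard errors ignore within-patient clustering of cells, as in the
  original reporting; intervals on real data would be anticonservative.
- Accuracy metrics are computed on development data unless a validation
  split is configured; no cross-validation utility is provided.
- The generator's effect magnitudes are package choices; headline
  real-data figures (AUC 0.95, 88%/84% sensitivity/specificity, 67%/79%
  k-NN accuracy, the patient-level validation percentages) depend on
  undeposited imaging data and are not reproduction targets here — only
  their arithmetic (delta-method tables, composition percentages) is.
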