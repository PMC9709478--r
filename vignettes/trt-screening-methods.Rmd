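---
title: "Screening bulk RNA-seq cohorts for patient-specific transcriptional read-through"
author: "trtscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bulk RNA-seq cohorts for patient-specific transcriptional read-through}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtscreen)
```

## Background and model

Transcriptional read-through (TRT) is the continuation of transcription
past a gene's transcription termination site (TTS), producing
downstream-of-gene transcripts. It is induced by cellular stresses —
viral infection prominently among them — and, when the read-through
transcript runs across the intergenic gap into the next gene, it can
change the apparent expression of that downstream gene. In a
patient/control cohort design, read-through shows up as patient-specific
coverage of an intergenic interval that is quiet in healthy controls,
together with elevated expression of the downstream gene of the pair.

`trtscreen` operationalizes this as a four-step screen over *adjacent
gene pairs*:

1. **Candidate enumeration.** Per chromosome, genes are sorted by
   position and each consecutive non-overlapping pair defines an
   intergenic gap. A gene can act as the "upstream" partner only if its
   TTS borders the gap: a `+` gene on the left of the gap or a `-` gene
   on the right. Same-strand neighbours give one *cis* pair; convergent
   opposite-strand neighbours give two directed *trans* pairs (the gap
   can be entered from either side); divergent neighbours give none.
2. **Active upstream gene.** In each patient, a pair is kept only when
   its upstream gene's FPKM is strictly above the 25th percentile
   (linear interpolation) of upstream FPKM over all candidate pairs in
   that same patient — read-through arises at actively transcribed
   genes.
3. **Intergenic signal.** The patient's intergenic FPKM must exceed 5
   times the mean intergenic FPKM of the healthy controls (written
   FPKM\*), evidence that transcription actually ran past the TTS.
4. **Downstream effect.** The downstream gene must respond: FPKM > 1.5
   when its control mean is zero, otherwise a fold change > 1.5 over the
   control mean.

A pair×patient call is the conjunction of steps 2–4. Pairs called in
strictly more than 30% of patients are *recurrent*; the per-patient
count of positive pairs (cis, trans, and the union of unordered gene
pairs, "total") is the patient's TRT *burden*. All fold-change and
percentile comparisons are strict, matching the screen's definitions.

Quantification follows coverage-tool semantics: a *fragment* (outer span
of a read pair, or a single unpaired read) counts toward a feature when
they overlap by at least 1 bp, on matching strands when the library is
strand-specific (the default; intergenic intervals are counted on the
upstream gene's strand). FPKM is
`count / ((length_bp/1000) × (library_size/1e6))` with the library size
equal to the sample's retained fragment count.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `upstream_percentile` | 25 (%) | step-2 activity floor, per patient |
| `intergenic_fc_min` | 5 (fold) | step-3 intergenic fold change over FPKM\* |
| `downstream_abs_min` | 1.5 (FPKM) | step-4 absolute branch (control mean 0) |
| `downstream_fc_min` | 1.5 (fold) | step-4 fold branch |
| `recurrence_min_frac` | 0.30 | recurrent-pair selection, strict |
| `zero_mean_epsilon` | 0 | optional pseudocount for step 3 |

Raising any threshold can only shrink the call set (nested calls), which
the test suite checks as a monotonicity property.

**Zero control baseline in step 3.** Silent intergenic regions make the
fold change 0/0 or x/0; the screen's definition does not cover this
case, so two explicit policies are provided. The default fails the pair
when both patient and control signal are zero, and otherwise compares
the patient FPKM against `intergenic_fc_min` times a *fallback unit* —
the smallest nonzero control intergenic mean across all candidate pairs
(1 FPKM if none exists), i.e. the faintest intergenic signal the cohort
can actually resolve. Setting `zero_mean_epsilon > 0` switches to a
conventional pseudocount denominator instead. Both are deliberate
choices in the face of a genuinely unspecified corner; the policy in
force is recorded in the screen's parameter record.

**Step-2 scope.** The percentile is computed per patient over the
upstream FPKM of all candidate pairs in that patient (not pooled across
the cohort). A per-patient threshold keeps the step meaningful when
library sizes or global expression levels differ between patients;
"above" is read strictly, so a degenerate patient in which all upstream
genes are equal keeps nothing.

## The NETosis activity score

The per-sample gene-set score is principal component 1 of the gene-set
× patient FPKM submatrix, restricted to set genes expressed (FPKM > 0)
in strictly more than half of the patients. Genes are z-scored before
the PCA by default: FPKM spans orders of magnitude and an unscaled PCA
would be dominated by the most highly expressed genes (`center` and
`none` are available since the choice is not dictated by the score's
definition). The sign of a principal component is arbitrary, so the
component is oriented by the convention that the majority of per-gene
Spearman correlations with the score are negative — under that
convention a *lower* score means *higher* gene-set expression, i.e.
more active NETosis. On an exact 50/50 split the component is flipped
when the sum of correlations is positive. Orientation never changes any
correlation magnitude, only signs.

## lncRNA target prediction

Cis targets are protein-coding genes whose bodies lie within 50 kb
(configurable) of the lncRNA's gene span on the same chromosome; strand
is ignored and distances are signed edge-to-edge gaps (0 on overlap).
The window is anchored on the gene span rather than the TSS because the
span is what a span-level annotation provides; with gene-sized windows
the difference is minor. Trans targets are all lncRNA × coding pairs
with |Spearman R| > 0.9 and p < 0.05 (both strict) across shared
samples, optionally intersected (AND, by default) with a
binding-evidence table such as triplex-prediction output.

## What the synthetic cohort emulates

`simulate_trt_cohort()` generates, from a single seed: a multi-
chromosome annotation with log-normal gene/gap lengths and random
strands; per-feature expected fragment counts (log-normal across genes,
Poisson across samples); planted read-through events; a co-regulated
NETosis block; and clinical traits coupled to the ground truth.

Planted events are drawn among pairs whose upstream gene sits above the
median baseline expression (mirroring the biology the screen's step 2
assumes) and are active in a patient with probability ~0.6. An active
cell receives intergenic coverage calibrated so the intergenic FPKM
fold change targets `readthrough_intensity` (default 10) and a
downstream-gene boost targeting `downstream_coupling` (default 3), both
modulated by a shared log-normal jitter (sd 0.25) plus downstream-only
noise (sd 0.3). The shared jitter is what couples intergenic and
downstream fold changes across patients; with the default noise levels
the median per-pair Spearman correlation over recurrent pairs falls in
the 0.7–0.9 band, the regime the screen is designed to detect. Because
fold changes are FPKM ratios and the planted signal itself inflates a
patient's library size, the calibration iterates the implied library-
inflation factor per patient to a fixed point; without this correction,
heavily burdened patients would systematically under-shoot their target
fold changes.

Fragment materialization places those counts as intervals: gene
fragments inside gene bodies on the gene strand, intergenic background
(Poisson, 6 expected fragments per interval — "leaky" transcription
that keeps control baselines resolvable) on the upstream strand, and
read-through fragments spanning TTS → gap → downstream-gene start on
the upstream strand. A spanning fragment therefore counts toward the
upstream gene, the intergenic interval and — for cis pairs, where the
strands match — the downstream gene, making the intergenic/downstream
coupling partly mechanical, which is precisely the interpretation the
screen embodies. For trans pairs the read-through transcript is
antisense to the downstream gene and does not contribute to its
stranded count; the downstream boost there is purely the induced
component.

Clinical traits use a Gaussian copula on the ground truth: normal
scores of the true burden (for NEUT%) or of the latent block-activity
variable (for PaCO2, PaO2/FiO2, and the virus/AKI labels via logistic
links) are mixed with independent noise at configured correlations
(0.4, 0.4, −0.35 by default) and mapped to plausible marginals.
Prognosis labels are drawn first at the cohort's death rate (26.8%),
and the death group's planting probability is multiplied by
`prognosis_effect` (default 2), so burden separates prognosis groups by
construction; setting it to 1 yields an exact null.

What the generator does **not** emulate: exon structure (gene spans
only), sequence-level reads and alignment error, GC/length bias, batch
effects, overdispersion beyond Poisson, and correlated co-expression
structure outside the NETosis block. Passing tests therefore show that
the screen and statistics behave correctly under the stated generative
assumptions — not that those assumptions capture every property of real
cohorts.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF/GFF's 1-based
  inclusive convention is converted only at I/O boundaries.
* Percentiles use linear interpolation (`stats::quantile` type 7).
* Wilcoxon rank-sum tests use exact enumeration when both groups have
  n ≤ 10 without ties, and the tie-corrected normal approximation
  (without continuity correction) otherwise — at cohort scale the
  approximation is accurate and ties are common.
* Spearman p-values follow `stats::cor.test` (exact for small n without
  ties, approximation otherwise); no multiple-testing correction is
  applied to trait scans, which report raw p-values.
* Chi-square tests are uncorrected by default; Yates correction is a
  flag.
* Constant vectors make rank correlations undefined; they are reported
  as missing rather than 0. Zero-variance matrices are an error for the
  PCA score, as is z-scoring a zero-variance gene.
* All screen diagnostics are recorded even for cells failing an early
  step, so heatmap-style outputs can show why a cell failed.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at the
default cohort scale (~500 candidate pairs, 56 patients for the
clinical analyses, 40 for the screen-recovery replicates, 20 controls)
and at a reduced scale (2 chromosomes × 40–60 genes, 10–20 patients)
for per-module properties; brute-force oracle comparisons use ≤ 50
genes or ≤ 50 fragments, where exhaustive enumeration is exact and
fast. These sizes were chosen so every oracle remains exactly
computable while the cohort-scale checks still exercise the designed
operating point.

## Known limitations

* The screen thresholds interval-level FPKM; it does not estimate how
  far past the TTS transcription continues.
* Gene spans stand in for transcript models, so read-through into an
  annotated but unexpressed isoform extension is indistinguishable from
  intergenic signal.
* Convergent trans pairs are emitted in both directions; whether a
  deduplicated orientation is preferable depends on the question, so
  the burden computation collapses directions only in the "total"
  union.
* The per-patient step-2 percentile and the zero-baseline step-3 policy
  are defensible readings of an underspecified procedure; both are
  configurable rather than hidden.
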