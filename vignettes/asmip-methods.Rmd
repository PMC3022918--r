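---
title: "Splice scores for junction-probe assays: models, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice scores for junction-probe assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmipr)
```

## The measurement model

Molecular inversion probes targeted at exon–exon junctions produce, per
gene `g`, a two-way table of log2 signals indexed by measurement row
(junction `j`, tag `k`) and tissue column `i`:

$$\theta_{j,k,i,g} = p_{j,k,g} + t_{i,g} + \varepsilon_{j,k,i,g}.$$

`p` is the probe effect — a sequence-driven bias of one probe tag, constant
across tissues and often larger than any biological signal; `t` is the
tissue-specific expression baseline of the gene; `ε` is mean-zero noise.
Alternative splicing adds a junction-and-tissue-specific shift `δ` on top.
Both scores in this package are estimates of `δ` in units of a robust
per-gene scale; they differ in how they estimate `p` and `t`.

Each junction is measured twice (two probe tags on arrays/sequencing, two
primer sets for qPCR), and the two measurements are averaged after
probe-effect removal precisely because they differ; a missing measurement
simply reduces the average to the informative one (`n_tags_used` records
which happened).

## Preprocessing

**Array background** (`subtract_background`): per array (one tissue at one
dilution) the background is the mean of the unused control features and its
SD their sample SD (n−1; the rule's source does not specify the
denominator, and at n = 20 the difference is negligible). Probe values are
reduced by the background, and corrected values at or below `z = 1.96`
times the SD are excluded. The rule is applied per array, not pooled across
the dilution set — each array has its own hybridization background.

**Dynamic range** (`select_dilution`): arrays are hybridized at three
sample volumes differing ten-fold, because a chip's linear range spans only
about two orders of magnitude. For each (gene, tissue) the dilution with
the most values strictly between the background threshold and the
`upper = 3500` fluorescence-unit ceiling wins; ties break toward the lowest
volume (least saturation risk). Saturated values in the winning dilution
are dropped rather than clamped — a clamped value would bias the additive
fit. Choosing different dilutions for different tissues offsets their
columns by log2 of the volume ratio; the scores' baseline removal absorbs
this (see *Invariances*).

**Log transform** (`log_transform`): array and sequencing values become
`log2(value)`. Zero counts are masked rather than pseudocounted — the
additive model was verified only at ≥ 4 reads per tag, below which tags are
retained but flagged `low_confidence`; a `pseudocount` option exists,
default off. qPCR cycle thresholds are already log2-scaled with slope −1,
so they enter as `θ = −Ct`; the reference difference `θ_i − θ_REF` then
equals the conventional ΔCt = Ct_REF − Ct_tissue. (The source describes the
subtraction in both orders in different places; the Methods formula is the
one implemented.) By the additive-shift invariance below, fitting the
M-score on `−Ct` rather than per-junction ΔCt changes nothing.

## The two scores

**R-score** (reference-based, `r_score`). `d = θ_i − θ_REF` against a
pooled many-tissue reference cancels `p` exactly; subtracting the mean `d`
of the gene's constitutive junctions (same tag, same tissue) cancels the
expression baseline; the tag average `f̄` is divided by `s_g`, a robust
scale of the constitutive `f̄` pooled over tissues. The constitutive mean
is the arithmetic mean (the formula's bar notation); robustness is confined
to the scale, where the package default is MAD × 1.4826 with an SD fallback
when the MAD degenerates to zero, and `scale = "huber"` offers an iterated
Huber scale for users wanting an M-estimator. A gene needs the reference
tissue plus at least two constitutive junctions with data; otherwise it is
skipped with a warning. A zero scale makes the gene's R-scores undefined —
they are dropped, never ±Inf.

**M-score** (model-based, `m_score`). Per gene, the (junction, tag) ×
tissue matrix — the reference, if present, is an ordinary column — is fit
by Tukey median polish; the residuals `f*` estimate `δ + ε`, and the score
is the tag-averaged residual divided by `s*_g`, the MAD (× 1.4826) of all
residuals of the gene. This needs no reference and no constitutive
annotation, at the price that the baseline is defined by the sample set at
hand. Genes need ≥ 2 junctions and ≥ 2 tissues with data. Exactly additive
input gives all-zero residuals, hence `s* = 0` and undefined scores —
reported by dropping the gene with a warning, never as NaN.

### Median polish numerics

`median_polish` alternately removes row and column medians from the
observed cells, **rows first**, and stops when the proportional reduction
of the sum of absolute residuals (SAR) in one full sweep falls below `tol`
(default 0.01, conventional for the algorithm) or after `max_iter` (default
10) sweeps. Missing cells never enter a median and stay missing. The
decomposition `x = overall + row + col + residual` is exact at every
observed cell at every iteration, by construction.

Two numerical facts worth knowing:

* The SAR can plateau exactly (zero reduction in a sweep) one or two sweeps
  before the residual matrix itself stops changing. Any implementation of
  the SAR stopping rule — including this one — can therefore return
  residuals that differ from a run-to-fixed-point polish by more than the
  tolerance. The test suite's independent brute-force oracle applies the
  same published stopping rule, and the two agree to < 1e-6 across random
  matrices with missing cells.
* The default `tol = 0.01, max_iter = 10` is a fit accuracy choice, not a
  score definition; the invariance tests run at `tol = 1e-12,
  max_iter = 200` because they assert properties of the converged fit.

### Invariances — what is exact and what is not

The assay's central normalization claim is probe-effect invariance: adding
any constant to all tissues of one (junction, tag) row changes no R-score
and no M-score. For R-scores this is algebra (the reference difference
cancels the row constant). For M-scores it is also exact at any iteration
count: the very first row-median sweep absorbs a row constant entirely.
The suite asserts both at 1e-9 on noisy simulated data.

Expression/dilution offsets — a constant added to one (gene, tissue)
column — are exactly absorbed by the R-score's constitutive mean (asserted
at 1e-9 on noisy data). For the M-score the column shift is just a change
of the baseline `t`, so on data that follow the additive model the polish
residuals (the score's numerator, and the input to its scale) are exactly
invariant; the suite asserts this at 1e-9 on noiseless model-form data.
Away from model form, however, a column shift can change which order
statistics the medians select, so the fitted residuals move by an amount
of the order of the noise — the invariance is approximate, not exact, and
no implementation of median polish can make it exact. The suite bounds the
resulting M-score perturbation well below the call cutoff on noisy data
instead of asserting 1e-9. One consequence: the suite checks the *exact*
column-shift invariance on sparse-delta noiseless genes, whose residual
MAD is zero by design (most residuals are exactly zero), so the comparison
is made on the residuals `f*` rather than on the undefined scaled score.

## Cutoffs and calls

`derive_cutoff` computes `|mean| + 3 SD` of a baseline score set and
applies it symmetrically (score symmetry for positive and negative changes
is assumed). The baseline defaults to constitutive junctions — the cutoff
marks the boundary of the constitutive distribution — with
`baseline = "all"` available because the published qPCR cutoffs do not
state which set the moments were taken over; both modes are provided and
neither is asserted as canonical. Cutoffs are stored at full precision; the
one-decimal values seen in print (5.7, 2.7) are display rounding.
`make_calls` uses strict inequalities: a score exactly at ±cutoff is called
0 (the boundary convention is unspecified in the source; strictness was
chosen so a degenerate cutoff of 0 still leaves zero scores uncalled). The
fixed asMIP cutoff is 1.3 for both array and sequencing readouts, kept
equal across platforms to make them comparable.

`binarize_calls` converts ternary calls on two sides to non-zero-vs-zero,
but a pair only counts as a true positive when both calls share the sign;
opposite-sign pairs are recorded as discordant and count as errors on both
ROC axes — this is why cross-platform ROC curves need not reach (1, 1).

## Evaluation

`concordance_auc` is the concordance index — the probability a random
positive outranks a random negative, ties at half credit — computed by
midranks, hence exact and invariant under strictly increasing transforms;
it equals the trapezoidal area under the full ROC curve (`roc_points`).
`sens_spec` counts concordant calls over truth positives and negatives.
`correlate_scores` always reports both Pearson and Spearman coefficients,
because the published account uses both labels for its correlations without
stating which; no resolution is asserted.

For control-based evaluation, scores are compared between a pair of tissues
chosen per gene (the pair known to expose the gene's splicing, e.g.
skeletal muscle versus stomach for tropomyosins): `tissue_pair_scores`
returns `|score_A − score_B|`, which is itself a splice score with the
baseline shifted to the pair. On synthetic data `truth_pair_map` selects
the most informative pair from the ground truth, and `truth_pair_labels`
marks junctions with differing `δ` inside the pair as positives and
globally constitutive junctions as negatives; alternative junctions
quiescent in the chosen pair are excluded, as they are not controls for
that pair. At the generator's default effect size (δ = 2.5, noise 0.4) the
acceptance suite requires a median tissue-pair AUC ≥ 0.95 over 50 seeds; at
δ = 3 × noise the property suite asserts a median AUC > 0.8 — the shared
tissue-effect estimation error inflates constitutive pair scores, and
claims of > 0.9 in that regime did not reproduce here.

## The synthetic generator

`sim_config` defaults describe the assayed design: 17 genes with 10–20
junctions each, five tissues (placenta, skeletal muscle, stomach,
cerebellum, frontal lobe) plus a pooled reference, 30% of junctions
alternative, splicing shift |δ| = 2.5 log2 units, probe-effect SD 1.0
(probe effects visibly dominate raw junction counts), tissue baselines
uniform over ±2 log2 units, noise SD 0.4, and sequencing depth scaled to
~100 expected reads at θ = 0 (the study's median tag count was of this
order). The reference is simulated as a tissue with all δ = 0, mirroring a
many-tissue RNA mixture that approximates baseline splicing.

Each alternative junction shifts in 1–2 of the five tissues
(`alt_tissue_range`). The choice is biological, made before any test was
run: the assayed control events are tissue-specific — muscle-specific
isoforms appear in one to two of the five tissues, neural-specific ones in
two — and a δ spanning most tissues would not be "tissue-specific" splicing
but a different baseline. It also matters statistically: a shift occupying
half or more of a row is partially absorbed by the row median, which is a
genuine limitation of the estimator for broadly-shared splicing (see
*Limitations*).

Counts are Poisson around `depth × 2^θ` by default; `nb_dispersion`
switches to negative binomial, as the count overdispersion of the real
assay is uncharacterized — this is a knob, not a claim. Arrays draw a
fresh Gaussian background per feature (mean 100, SD 15), clamp at the 3500
saturation ceiling, and carry 20 unused background-only features per chip;
the gain is auto-scaled so the mid dilution places the median probe
mid-range, since only the ceiling, not the gain, is published. qPCR renders
`Ct = 30 − θ + noise` — slope −1 and nothing else (no PCR-efficiency
model) — with whole-primer-set dropout at the configured probability.

What the generator does **not** emulate: cross-hybridization between
probes, sequence-level effects (probe effects are i.i.d. Gaussian, not
sequence-derived), spatial array artifacts, count overdispersion beyond the
optional NB, or correlated noise between the two tags of a junction. A
green test therefore establishes that the pipeline's statistics behave as
designed under the additive model with realistic magnitudes — not that the
method would survive every artifact of a physical assay.

## Degenerate inputs and conventions

* Background SD of 0 (identical unused features): only corrected values
  ≤ 0 are excluded.
* A (gene, tissue) with no in-range array data at any dilution: all values
  missing, with a warning.
* Negative counts or array intensities: an error, not silent masking.
* Zero robust scale (R or M): gene's scores undefined and dropped with a
  warning.
* A junction whose both qPCR primer sets fail: absent from the ΔCt output.
* All randomness derives from one top-level seed with fixed per-stage
  offsets, so every renderer and the whole pipeline are bit-reproducible
  for a given config.

## Limitations

* Splicing shifts shared by half or more of the tissue columns are
  partially absorbed into the probe-effect estimate by the row median; the
  M-score systematically underestimates such broad shifts and can invert
  their apparent sign in unshifted tissues.
* The scaled M-score's invariance to per-tissue offsets is approximate
  away from the additive model (order of the noise), as discussed above.
* Scores are per-junction; no isoform deconvolution or multi-gene joint
  modelling is attempted, and no multiple-testing machinery is layered on
  the calls (the upstream analysis used none).
* qPCR modelling stops at slope −1; amplification-efficiency differences
  between primer sets land in the probe-effect term.
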