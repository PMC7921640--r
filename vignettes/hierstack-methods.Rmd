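---
title: "Hierarchical classification with hierarchy transfer learning and stacked multimodal ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical classification with hierarchy transfer learning and stacked multimodal ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical image classification tasks often pair a relatively easy
*detection* question (is this eye normal or diseased?) with a much harder
*subtyping* question (which of `n` disease subtypes is it?), under severe
label scarcity: a few hundred expert-labelled cases, imbalanced across
classes.  The motivating system is glaucoma management, where optic-disc
morphology is graded into four subtypes (focally ischemic, generalized
enlargement, myopic, senile sclerotic) from several two-dimensional views
derived from one volumetric OCT scan — a projection image, an en-face
image, and horizontal/vertical B-scans through the disc.  A flat
`(n + 1)`-class classifier must learn both questions at once from the same
small sample.

`hierstack` implements a two-step training framework that mirrors the
clinical workflow instead:

1. **Hierarchical classification (HC).**  A *low-level* binary network is
   trained to separate normal from diseased cases on the full training
   set.  A *high-level* `n`-class network is trained on the diseased cases
   only.  Their outputs are combined by a linear metamodel.
2. **Hierarchy transfer learning (HTL).**  The high-level network is not
   initialised from a generic pretrained model but from the *trained
   low-level network*: whatever features were learned for disease
   detection are reused as the starting point for subtype discrimination.
   This is where the small-data gain is expected — the second task starts
   from on-task features rather than generic ones.
3. **Stacking.**  One bundle is trained per input modality; their
   confidence vectors are concatenated and a second-level linear
   support-vector machine learns the final decision.  A multiple-input
   network (one convolutional trunk per modality, features concatenated
   before the dense head) is the natural comparator.

## Model components

### Confidence vectors

For a hierarchical bundle the per-case confidence vector is

\[ c = (\, p_\text{low}(\text{normal}),\; p_\text{high}(s_1), \dots,
      p_\text{high}(s_n) \,) \in \mathbb{R}^{n+1}, \]

the low-level model's normal probability followed by the high-level
softmax over subtypes (which sums to 1; the full vector intentionally does
not).  Flat bundles contribute their full `(n+1)`-class softmax instead.
Stacking `M` modalities concatenates `M` such blocks into a vector of
length `M (n + 1)`, in the fixed block order the bundles are supplied in
(conventionally projection, en-face, discH, discV).

### The metamodel

The combiner is a linear max-margin classifier: one binary soft-margin SVM
(cost `C = 1`, no rescaling, via libsvm) per class, one-vs-rest, with the
class decided by the largest decision value.  Decision values double as
ROC scores.  `C`, like everything else, is exposed; the default follows
common practice since the 5- or 20-dimensional confidence space gives the
problem very low capacity anyway.

The confidences the metamodel is *fitted* on can be produced two ways:

* `meta = "oof"` (function default): `k`-fold out-of-fold generation — the
  base networks are refitted on `k - 1` folds, held-out confidences are
  collected for the remaining fold, and the final base networks are then
  refitted on all training cases.  This is standard stacking hygiene; it
  avoids fitting the combiner on optimistically overconfident in-sample
  probabilities.  The default is 5 folds.
* `meta = "naive"`: in-sample confidences from the final base networks.

The shipped desk-scale benchmark uses `meta = "naive"`.  At 45–180
training cases, fold-refitted base models lose a third to a half of their
already tiny training sets, and the resulting meta-stage noise was the
dominant variance component in pilot runs — larger than the strategy
differences under study.  In-sample fitting does not bias the reported
numbers (all evaluation happens on untouched test cases); its only risk is
a mildly overfitted combiner, which affects every strategy equally.  At
clinical scale the out-of-fold default is the right choice.

### The convolutional backbone

No deep-learning framework is assumed: the package ships a compact,
fully seeded convolutional engine written against base R's BLAS.  The
architecture is a scaled VGG-style stack — `n_blocks` repetitions of
conv3×3/ReLU, conv3×3/ReLU, max-pool2 — followed by one dense ReLU layer
and a softmax.  Convolutions are evaluated as im2col index gathers plus
matrix products, so the heavy lifting is three or four GEMMs per layer.
Training is minibatch RMSprop (momentum-free adaptive steps, decay 0.9)
on class-weighted cross-entropy; weights default to
`total / (n_classes * class_count)`, so minority classes are not drowned
by the majority.  He-normal initialisation, shuffling, and augmentation
draws all flow from one seed per run: identical data, control and seed
give bit-identical final weights, which is what makes the transfer
contracts testable exactly.

Transfer (`hs_transfer()`) copies every convolutional-block parameter
bit-exactly and re-initialises the dense head for the new class count; the
copied region is exactly the region `freeze_blocks` can later hold fixed.
The default fine-tunes everything (`freeze_blocks = 0`), since the right
fine-tuning depth is data-dependent and the engine exposes it rather than
fixing it.

Generic pretraining is modelled by a synthetic *pretext task*
(`hs_pretext()`): classifying simple geometric shape classes — discs,
rings, bars, crosses — at random positions and scales under noise.  It
plays the role that a large natural-image corpus plays at full scale:
providing a source of generic edge and blob detectors for transfer.
Skipping it (random-initialisation source) stays available as a baseline,
and `hs_set_weights()` accepts externally supplied weights for anyone who
has real pretrained parameters in hand.

### Evaluation statistics

Class imbalance makes raw accuracy misleading, so the package reports:

* **Cohen's kappa** — chance-corrected agreement
  \((p_o - p_e)/(1 - p_e)\) with \(p_e\) from the marginal products; the
  degenerate case \(p_e = 1\) (both raters constant on the same class)
  returns 1.
* **Weighted (balanced) accuracy** — the unweighted mean of per-class
  recalls.
* **Relative kappa / performance reduction** — a strategy's kappa divided
  by the hierarchy-transfer strategy's kappa at the same training
  fraction (reported to 3 decimals), and `(1 - relative) * 100` percent
  (1 decimal).
* **One-vs-rest ROC AUC** with midrank handling of ties, macro-averaged
  over classes; a class absent from the truth is excluded from the macro
  average with a warning rather than zero-filled.  For hierarchical
  bundles the ROC scores are the metamodel's per-class decision values;
  for flat bundles, the softmax.
* **Paired two-tailed t-tests** between strategies across replicate
  splits.  With the conventional three replicates the test has two degrees
  of freedom and is fragile; it is reported as-is, and the learning-curve
  orderings are the more robust evidence.

## The synthetic benchmark

The clinical images cannot ship, so the package generates a multi-modal
surrogate whose *class structure* makes the framework's three claims
testable; it does not attempt OCT physics, retinal layers, or volumetric
geometry.

Each case carries one grayscale image per modality: iid Gaussian noise
around a gray background, plus, for diseased cases,

* a **disease-common signal**: a smooth centred disc blob (amplitude
  `disease_signal_strength[m]`), shared by all subtypes — this is what
  makes normal-vs-disease knowledge transferable to subtyping; and
* a **subtype-specific signal**: an angular sector *of that same disc*
  (half-width 50°) at a subtype-specific orientation, 90° apart for the
  four default subtypes (amplitude `subtype_signal_strength[m]`).

Making the subtype code an angular modulation of the disc, rather than a
structure elsewhere in the image, is deliberate: the low-level model's
disc-localised features are then maximally reusable for subtype
discrimination, which is the mechanism hierarchy transfer exploits.  An
earlier design with a narrow off-disc rim wedge was discarded during
development because the desk-scale network could not learn it at all
while the matched-filter oracle solved it easily — a pathological gap
between oracle and learnable difficulty.

Per-modality amplitudes are set so that the *difficulty ranking* of the
four modalities mirrors what is typical for these image types — en-face
easiest, projection close behind, the horizontal disc B-scan harder, and
the vertical disc B-scan deliberately weak (signal strengths about a
third of the others).  The weak modality gives the stacking ensemble
measurable headroom: a combiner that merely averaged would be dragged
down by it.  Only the ranking is designed; the absolute magnitudes are a
property of this synthetic task, not of any clinical dataset.

`oracle_classify()` is the generator's brute-force ground truth: the
Gaussian maximum-likelihood matched filter over the noiseless class
template stacks.  It is exact on noiseless data, approaches chance when
noise dwarfs the signals, and its Monte-Carlo accuracy on the benchmark
configuration is the ceiling no trained model should beat by more than
sampling error.

What passing the synthetic checks does **not** show: robustness to
acquisition artefacts, anatomical variability, label noise, or
patient-level correlation (the split unit is the case; no patient grouping
is modelled because none is represented in the generator).  The benchmark
demonstrates that the *training framework* behaves as claimed when its
assumptions hold, not that any particular clinical performance level is
reproduced.

## Data handling

* **Stratified splitting** allocates `round(count * test_fraction)` cases
  per class to the test side — rounding half away from zero, since R's
  `round()` half-to-even would make the worked examples irreproducible —
  and repairs any stratum that would be empty on either side.  The
  default is three shuffled 80/20 replicates.
* **Fraction subsampling** keeps `round(count * fraction)` (at least 1)
  training cases per class; test cases are never touched, and
  `leakage_audit()` re-checks every experiment by case id.
* **Augmentation** is applied on the fly each epoch: optional horizontal
  flip, rotation within ±10°, shift within ±5% of the image size, as one
  bilinear affine resampling, clipped to `[0, 1]`.  The *benchmark*
  disables flips: the synthetic subtype code is an orientation, so a flip
  is not label-preserving there.  For real images the generic default
  keeps flips on.
* **Seeds**: one master seed expands into per-purpose child seeds
  (`child_seed(master, purpose, index)`) for simulation, pretraining,
  splitting, subsampling, and each bundle fit, so whole experiments are
  reproducible while stages stay independently re-runnable.

## Shipped experiment sizes

The default benchmark (`hs_benchmark_config()`) scales the clinical class
imbalance down to 40/30/60/70/25 cases (225 total) at 24×24 pixels, with
a 2-block 6/12-channel network (dense width 24), 12 epochs of RMSprop at
learning rate 2e-3 and batch size 16, and a 6-epoch pretext source.
These sizes are the package's chosen desk-scale operating point: large
enough that all three claimed orderings are measurable over a handful of
seeds, small enough that the full grid — three strategies, four
modalities, stacking, the multiple-input comparator, and a 7-point
learning curve — runs in minutes on one CPU.  The clinical scale (full
VGG-16 geometry, hundreds of cases, larger images) remains reachable
purely through configuration.

Open design points were resolved as follows: each learning-curve fraction
reuses its replicate's split (only the subsample varies), so curves are
comparable within a replicate; the multiple-input network concatenates
per-trunk features after the last convolutional block with no trunk
weight sharing (modalities differ in appearance); subtype order is fixed
as (FI, GE, MY, SS) everywhere; ties in argmax decisions break towards
the first class in class order.

## Limitations

* The t-tests over three replicates are fragile by construction and
  reported for completeness; directional orderings over seeds are the
  meaningful checks at desk scale.
* SVM decision values are scores, not calibrated probabilities; no
  probability calibration is attempted (ROC analysis does not need it).
* The hierarchy is exactly two levels; deeper taxonomies are out of
  scope.
* The generator's per-modality difficulty is a designed ranking, not a
  fit to any measured modality-wise performance.
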