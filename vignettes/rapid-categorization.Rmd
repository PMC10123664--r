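---
title: "Modelling ultrafast image categorization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultrafast image categorization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rapidcat)
```

## The task and the model

Humans report the presence of an animal in a briefly flashed photograph with
high accuracy in well under 200 ms — fast enough that processing must be
essentially feed-forward. `rapidcat` models this go/no-go categorization with
convolutional networks: a VGG-style backbone (stacked 3×3 convolutions with
rectification, max pooling between blocks, adaptive average pooling to a
fixed spatial side, then fully connected layers) emits a single score
interpreted as the probability that a *superordinate* category — a synset
such as 'animal' or 'artifact' — is present, and a balanced target/distractor
test set turns that score into an accuracy via the strict rule
`decision = target iff score > 0.5`, with

\[
\mathrm{Accuracy} = \frac{TP + TN}{TP + TN + FP + FN}.
\]

Tasks are *defined* by a lexical hierarchy, not by a fixed label list: a
directed acyclic graph of hyponym→hypernym ("is a kind of") edges over
synsets, with the image-class labels as designated leaves. A leaf is a target
label for synset $s$ exactly when some hyperonym path from the leaf to a root
passes through $s$; the remaining leaves form the distractor pool. Two
consequences of this definition are used throughout:

* **Dataset construction** (`build_dataset()`): balanced train/validation/test
  splits (defaults 2000/800/1200 images, half targets each) sampled
  two-stage — a label uniformly from the pool, then an unused image uniformly
  from that label — so populous labels do not dominate, with image-level
  disjointness across splits.
* **Look-up-table (LUT) scoring** (`lut_probability()`): a pre-trained
  K-class leaf classifier scores a superordinate synset as the **sum of its
  post-softmax leaf probabilities over the synset's descendants**, with no
  re-training at all.

Five (re-)training protocols are implemented (`protocol()`): SLS (random
initialization, all layers train), TLC (pre-trained backbone, only the final
classifier layer trains), TLA (pre-trained, all layers train), and TLDA/TLAA
(TLC plus stochastic augmentation — respectively a fixed chain of flips (p =
0.5 each), a full-range rotation (p = 1) and grayscale (p = 0.5), or one of a
16-operation affine/photometric catalogue per image). Training minimizes
sigmoid-linked binary cross-entropy with momentum SGD; the retained default
hyperparameters are batch size 8, learning rate 5·10⁻⁵, momentum 0.99, 25
epochs, selected by a one-at-a-time validation sweep (`sweep()`).

## The synthetic image generator

Nothing in the pipeline depends on a particular image provider, but the
shipped generator (`synthetic_spec()`, `make_source()`) supplies procedural
images whose statistics carry the structure the analysis assumes, so every
experiment runs at desk scale with no download:

* **animal-like leaves** draw curved, isotropic contours (rings whose radius
  scales with the 'cue scale');
* **artifact-like leaves** draw straight strokes of matched stroke profile —
  vertical by default, so the cue is orientation-anisotropic, or uniformly
  oriented with `rotation_invariant = TRUE`, in which case only the
  *arrangement* (curved vs straight at the cue scale) separates the classes;
* **neutral leaves** carry background clutter only.

Leaves within a branch are separated along a subordinate continuum (ring
radius, stroke length), which is what makes K-class pre-training a
non-trivial task, exactly as leaf labels differ within 'animal' in
photographic collections. Nuisance variation covers element position and
scale and per-channel colour gain; each image is standardized in luminance so
mean level and global contrast carry no class information. Two dials matter
for the experiments:

* `cross_category_exclusion` (default 0.9): the probability that an image
  carries only its own branch's cue; otherwise the opposite branch's cue is
  superimposed. This reproduces, in controllable form, the anti-correlation
  of animals and artifacts within photographs that drives the cross-task
  bias. The default is deliberately below 1 so cross-task accuracies are
  high but imperfect.
* `signal = FALSE`: pixel content becomes independent of the label — the
  clean chance control for the 500-label "random task".

What the generator does **not** emulate: photographic content, occlusion,
context, within-class texture diversity, or any semantic relation between
leaves beyond the branch structure. Passing tests therefore certify the
*pipeline logic* (dataset construction, training mechanics, scoring,
transform batteries) and the *qualitative* phenomena (separability, chance
controls, rotation sensitivity and its cure by augmentation, patch-shuffle
collapse below the cue scale, cross-task bias), not photographic accuracy
values.

A model-free linear probe on oriented-energy features
(`orientation_features()`, `linear_probe()`) grounds the generator: ≥ 0.9
accuracy on the default task, chance on the no-signal control, monotone in
`cue_contrast`, and broken by 90° rotation exactly when the cues are
anisotropic.

## Study conditions at desk scale

The experiments in `analysis/` and the acceptance script run under fixed
desk-scale conditions chosen once: 64-px images (side must be divisible by
32 so the patch-shuffle grids exist), 16-px cue scale, 10 leaves (4 animal,
4 artifact, 2 neutral), 200/80/120 splits, the published training
hyperparameters, and the small backbone preset (three 3×3 convolutions of
8/16/32 channels, adaptive pooling to 4×4, one hidden layer of 64 units).
Pre-training uses 30 images per leaf for 15 epochs at learning rate 0.01,
momentum 0.9 — the desk-scale stand-in for large-scale pre-training, and the
K-class model behind LUT scoring. The full default backbone (13
convolutions in 5 blocks, 64→512 channels, 7×7 adaptive pooling) is
constructed and exercised structurally, and accepts externally supplied
weights (`make_backbone(weights = ...)`) when shapes match.

## Numerical and design choices

* **Rotation.** Angles at exact multiples of 90° are lossless grid
  operations (transposition/reversal); other angles resample bilinearly
  (configurable to nearest) about the image centre with out-of-frame pixels
  set to black. The full frame is kept — no crop. This makes the cardinal
  angles of the rotation sweep interpolation-free, which is why they are
  special in the accuracy-vs-angle curves.
* **Thresholds.** "Greater than" is strict: a score exactly at 0.5
  classifies as distractor. Probability vectors offered to the LUT must
  already be normalized (within 1e-6); raw scores are rejected rather than
  silently renormalized.
* **Pruning.** Depth removal is per convolutional layer (the deepest first),
  with a block's pooling stage removed when the block empties; adaptive
  pooling keeps the classifier's spatial input constant, and the first
  fully connected layer is re-instantiated to the surviving channel width
  (hidden and output widths unchanged). Removing individual layers rather
  than whole blocks is the only reading under which twelve distinct pruning
  depths exist for a 13-layer stack. `prune_conv_layers(model, 0)` is the
  exact identity.
* **Freezing.** `head_only` marks exactly the final classifier layer
  trainable; frozen parameters are bit-identical after training (asserted in
  tests). When nothing below the head trains and no augmentation is active,
  the penultimate features are computed once and only the head iterates —
  mathematically identical, much faster.
* **Custom augmentation's rotation range.** The chain's mandatory rotation
  draws uniformly from −180°..180°, matching the evaluation sweep's range.
* **The auto-augmentation catalogue** is a fixed, documented set of 16
  operations (rotation ±30°, two shears, two translations, scale, two
  flips, contrast, brightness, sharpness, posterize, solarize, grayscale,
  cutout, identity), one drawn per image with a random magnitude,
  deterministic under seed. Because a single mild operation is drawn per
  image, TLAA preserves clean accuracy but buys much less rotation
  robustness than TLDA — visible in `analysis/04_robustness.R`.
* **Cross-task cells.** A detector evaluated on a genuinely different task
  is read as predicting its own synset's *absence* (its decision is
  complemented): within anti-correlated category pairs, "no animal here" is
  the informative prediction for "artifact present", and this is precisely
  the dataset-composition bias the cross-task matrix quantifies. The
  uncomplemented accuracies are kept in the `direct` attribute of the
  returned table; on the strict datasets, whose distractors exclude the
  other superordinate, the complemented reading collapses to chance — the
  designed signature of the bias.
* **Sweeps** are one-at-a-time, never factorial, and the argmax per
  parameter is reported alongside the full table.
* **Agreement** between two responders is the fraction of images with
  identical correctness (both right or both wrong), plus the four-way
  taxonomy; a correlation-based statistic would be an alternative reading,
  and the fraction-identical definition is stated wherever the number is
  reported.
* **Exclusion lists.** Labels excluded by configuration (e.g.
  human-depicting labels, conventionally not counted as animal targets)
  leave both pools: an excluded descendant cannot be a distractor without
  violating the invariant that no distractor is a kind of the task synset.
* **Determinism.** Every stochastic step (splits, initialization, shuffling,
  augmentation, permutations) derives its seed from a master seed via an
  order-independent integer hash (`derive_seed()`), so a manifest is a pure
  function of its inputs and identical seeds give byte-identical results.

## Known limitations

* The backbone trains on CPU at desk scale; nothing prevents constructing
  the full 13-layer configuration, but training it to photographic quality
  is out of scope, and pruning experiments on the 3-layer preset lose
  accuracy per removed layer much faster than a 13-layer stack would.
* The generator's "random task" over few leaves keeps large accidental
  branch correlations; the label-pixel-independence mode is the faithful
  chance control at this scale (the 500-label condition this emulates
  averages those correlations out).
* Timing measurements (`timed_predict()`) are reported, never asserted:
  they are hardware-dependent. The monotone proxy — fewer layers, fewer
  parameters — is asserted instead.
* Human response ingestion (`read_responses()`) accepts any per-image CSV of
  truth/decision pairs; no psychophysical data ships with the package.
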