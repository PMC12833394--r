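---
title: "Adaptive anchoring for long-bone fracture detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive anchoring for long-bone fracture detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracdet)
```

## The problem

Two-stage object detectors of the Faster R-CNN family propose candidate
regions by scoring *anchors* — reference boxes laid at every position of a
feature grid — and then classify and refine the survivors. Over a feature
pyramid with strides 4 to 64 on an 800×800 radiograph this means 53,294
anchor positions and, at 3 anchors per position, 159,882 anchors per image.
For long-bone radiographs this is wasteful: the diaphysis sits near the
image centre, and fractures occur on the diaphysis. *Adaptive anchoring*
restricts the region proposal network (RPN) to a central window, cutting
the anchor budget by about two thirds without touching the regions where
fractures actually occur.

`fracdet` implements this restriction together with everything needed to
exercise it end to end at desk scale: brightness normalization,
bounding-box-aware augmentation, stratified splitting and class weighting,
a toy two-stage detector, a deterministic treatment-recommendation rule
engine, Grad-CAM saliency, detection metrics, and a synthetic radiograph
generator.

## The anchoring model

A pyramid level with stride $s$ on an $H\times W$ image has
$\lceil H/s\rceil \times \lceil W/s\rceil$ grid positions (ceiling
division, so the 13×13 grid at stride 64 matches the published count of
169). Two restriction modes are provided, and they are deliberately **not**
equivalent:

* **`table_consistent`** (default). Keep all grid rows and the centred
  block of $\mathrm{round}_{\uparrow}(0.33\,\mathrm{cols})$ columns, where
  $\mathrm{round}_{\uparrow}$ rounds half up. This rule reproduces the
  published per-level adaptive counts exactly
  (13,200 / 3,300 / 850 / 200 / 52 for strides 4–64 at 800×800;
  $0.33 \times 50 = 16.5 \to 17$ forces the rounding convention). Totals:
  17,602 positions, 52,806 anchors, a 67% density reduction.
* **`eq_region`**. Keep positions whose cell centres fall inside the
  rectangle $[x - 0.17w,\, x + 0.17w] \times [y - 0.34h,\, y + 0.34h]$
  about the region centre $(x, y)$ — the corner-coordinate form of the
  restriction. This window covers $0.34 \times 0.68 \approx 23\%$ of the
  image area, which is *smaller* than what the published per-level counts
  imply; the source material also describes the vertical trim once as
  16.5% per side (keeping 67%) and once, via the corner coordinates, as
  ±0.34h (keeping 68%). Both readings are faithful; the package makes each
  available and defaults to the one that matches the printed accounting.

Coordinates are pixel-based, origin at the top left, y increasing downward;
boxes are `(x_min, y_min, x_max, y_max)`, half-open on the max edge. The
region centre defaults to the image centre but is configurable, since
nothing fixes it in general.

Percentage reductions are reported as the arithmetic value
$(\text{standard} - \text{adaptive})/\text{standard} \times 100$, rounded
half up. For two pyramid rows the printed source values differ from the
arithmetic ones (P2: printed −40% vs arithmetic −67%; P6: printed −62% vs
−69%); the package reports the arithmetic values.

```{r}
anchor_budget(800, 800)
```

## Preprocessing

**Brightness normalization.** Radiographs off the archive are dark and
low-contrast. Each image is rescaled by its observed range and a scaling
factor $K$: $S = K\,(r - r_{\min})/(r_{\max} - r_{\min})$, so $K = 1$ maps
onto $[0,1]$ exactly, $K > 1$ brightens, $K < 1$ darkens. A constant image
has no dynamic range; it maps to all zeros rather than raising an error,
so batch pipelines survive blank frames. The output is invariant to affine
rescalings of the input, which the test suite checks property-style.

**Augmentation.** Isotropic scaling, rotation about the centre, a random
crop retaining 80% of each side, horizontal flip with probability 0.5, and
photometric jitter within ±20%. Every geometric step transforms the boxes
through exactly the same affine map as the pixels (rotation maps the four
corners and takes the enclosing axis-aligned box — the standard choice);
photometric jitter leaves boxes alone; boxes pushed outside the crop are
dropped and reported via the `kept` index. Rotation (±10°) and scaling
(0.9–1.1) ranges are free parameters whose defaults are chosen so a
diaphyseal fracture cannot leave the frame; the crop fraction, flip
probability and jitter magnitude are the protocol's stated values. All
draws come from a self-contained generator seeded per call, so a fixed
seed reproduces the output byte for byte without touching the global RNG.

**Splitting.** The 60:20:20 stratified split uses per-class
largest-remainder allocation. The published per-class rows imply two
different tie-breaking conventions (one class resolves leftovers toward
training, another toward validation/testing); no single rule reproduces
both, so the package fixes one — remainder ties prefer validation, then
testing — which reproduces the 1,004 → 602/201/201 row exactly. Stratified
k-fold partitioning deals each class round-robin (per-class fold sizes
differ by at most one); augmentation belongs inside training folds only.

**Class weights.** The published weight table (1.76, 0.92, 0.62, 0.92 for
supports 314, 602, 891, 602) is very close to $553/\text{support}$, which
matches no standard reweighting formula on those supports — inverse-mean
weighting would give 1.92, 1.00, 0.68, 1.00. The published numbers are
therefore shipped as a fixed lookup (`scheme = "paper_table"`), refused
for any other support vector, with `inverse_mean`
($\bar{n}/n_c$) as the derivable alternative.

## The treatment rule engine

Eligibility reflects the protocol's three assumptions: skeletally mature
patients, intact distal neurovascular status, open fractures at most
Gustilo–Anderson IIIA. Eligible descriptors are mapped by two ordered
rules: any impacted fracture → class IV (casting); otherwise the
(bone, diaphyseal third) pair selects the surgical method — proximal femur
→ fixed-angle device (I), mid-shaft femur/leg/humerus → intramedullary
nail (II), everything else including the whole forearm → plate (III).
Diaphyseal thirds are equal axial partitions with half-open boundaries
($[0,\tfrac13)$ proximal, $[\tfrac13,\tfrac23)$ mid, $[\tfrac23,1]$
distal); the boundary handling is the package's choice, as is the default
orientation (proximal end at the top of the image, configurable per
image). Morphology tags (displacement, comminution, complexity) are
carried in the descriptor and logged in the audit trail but fire no rules,
because no rule set over them is defined. The class numbering I–IV with
plate = III resolves a duplicated "II" in the source tables. Outputs are
benchmarking labels, not clinical advice.

## The toy detector

No deep-learning runtime is assumed: the detector is a small two-stage
network written directly in R — two 5×5 stride-2 convolutions (im2col
matrix multiplication, hand-written backward passes verified against
finite differences), giving a stride-4 feature map; a 1×1-conv RPN scoring
3 anchors per kept position with objectness and box deltas; and a linear
head over ROI-mean-pooled features. The kernel width matters: with 3×3
kernels the receptive field (7 px) cannot distinguish the dark fracture
gap from dark background, and training stalls.

Design notes, all visible in the code:

* The RPN position set comes from the anchoring module verbatim, so
  adaptive mode scores exactly the `table_consistent` subset (352 of 1,024
  positions at 128×128 — 34.4%).
* Anchor assignment: IoU ≥ 0.7 positive / ≤ 0.3 negative, plus the
  best-anchor rule so each image has at least one positive. The objectness
  loss balances its positive and negative arms 50:50, and half of the
  sampled negatives are hard negatives (highest current scores).
* The head's features append the box's normalized centre, size, and
  quadratic centre terms to the pooled activations. The treatment class
  depends on the diaphyseal third — an *axial position*, invisible to
  pooled local features — and "mid" versus "either extreme" is not
  linearly separable in the centre coordinate, hence the quadratic terms.
  The head also trains at 5× the shared learning rate; its geometry
  features are small relative to pooled activations and learn slowly
  otherwise.
* Detection confidence is RPN objectness × head class probability, the
  Faster R-CNN convention; NMS at IoU 0.5.
* The multi-task loss is class-weighted cross-entropy plus smooth-L1 box
  regression, each averaged over its contributing samples.

The optimizer is SGD with momentum 0.9 and weight decay 0.0001; the
learning rate decays by 0.1 every 10 schedule steps. Schedule steps are
**epochs**: a literal per-minibatch reading of "every 10 iterations" would
extinguish the rate within 30 steps, irreconcilable with multi-day
full-scale training runs. `optimizer_schedule()` defaults to the
full-scale base rate 0.001; `train_toy()` defaults to 0.01 (with the same
decay rule), because at toy scale — a two-layer backbone, 60 images,
20 epochs — the full-scale rate barely moves the weights. Backbone
identifiers for the clinical-scale ResNet/ResNeXt variants are accepted in
the configuration but have no trainable implementation here.

## Grad-CAM

At the last convolutional layer, channel weights are the global average of
the class-score gradient, $\alpha^c_k = \tfrac1Z \sum_{i,j}
\partial y^c/\partial A^k_{ij}$ with $Z$ the number of spatial positions,
and the heatmap is $\mathrm{ReLU}(\sum_k \alpha^c_k A^k)$. For a
detection, $y^c$ is the pre-softmax head logit of the selected box (the
pre- vs post-softmax choice is the package's); its gradient flows through
the ROI mean-pooling, so only pooled cells carry gradient mass. Heatmaps
are bilinearly resized to the image, min-max normalized, colour-mapped and
alpha-blended for overlay.

The randomization sanity check retrains **from scratch** (rather than
fine-tuning, which is the other defensible reading) on a corrupted copy of
the training split — labels permuted, images replaced by intensity-matched
Gaussian noise — and evaluates both models on the same intact held-out
split. "Near-chance" is operationalized as corrupted AP at most half the
intact AP.

## Evaluation

Matching is greedy and class-aware in descending score order (ties broken
by detection index), one truth per detection. AP integrates the all-point
interpolated precision-recall curve (the precision envelope); the 11-point
alternative is available, and the pooled AP is emitted alongside the
per-class mean (mAP) since either reading of "AP" is defensible. Bootstrap
confidence intervals resample whole images (n = 2000, percentile method,
95%) — the resampling unit, count and method are the package's choices, as
only the level is stated upstream. Site-stratified reports run the same
pipeline independently per acquisition-site label.

The demographic module packages the 1,410-patient cohort tables (gender ×
age, fracture location × age, injury mechanism × age) and recomputes the
headline shares: 63% male, 36.2% leg fractures, 48.7% road-traffic
injuries, and 52.4% of leg fractures in the 25–44 band against a printed
52.3 — the underlying ratio is 267/510 = 52.35%, a borderline half-up
rounding. Two printed subtotals in the source tables are internally
inconsistent (a femur row total of 405 against cells summing to 402, and
one bad-fall age cell); the fixture carries the per-age totals rows, which
are the mutually consistent set and sum to 1,410 in every margin, and the
validator rejects any table whose margins disagree.

## The synthetic generator

`make_radiograph()` renders a bright vertical diaphysis band with smooth
cortical edges on a dark noisy background and carves a fracture at a
parameterized axial position: a dark gap (transverse/oblique/spiral), a
half-width gap (greenstick), a gap with bright fragments (comminuted), or
a *brightened overlap* for impacted fractures, so the casting class is
visually distinct. The ground-truth box tightly encloses the
discontinuity, and the descriptor's diaphyseal third is consistent with
the axial position by construction.

`make_dataset()` samples (bone, third, pattern) combinations *per class*
so that the annotation label always equals `recommend(descriptor)` — the
generator cannot contradict the rule engine — and mixes classes
proportionally to the clinical totals 522 : 1,004 : 1,485 : 1,004
(largest-remainder apportionment; class I ≈ 13%). Output is PNG images, a
COCO-style annotation JSON (boxes as x/y/width/height), and an index CSV
mapping image files to class and acquisition-site labels.

What the phantoms are *not*: anatomically faithful. There is no soft
tissue, no joint structure, no projection geometry, no Gustilo soft-tissue
appearance, and bone-group identity is reduced to band width. Passing
tests on phantoms demonstrates that the pipeline's machinery — anchor
restriction, training dynamics, saliency localization, metric computation
— behaves as designed; it says nothing about clinical performance on
radiographs, which requires the private clinical data and GPU-scale
training that are explicitly out of scope here.

## Problem sizes and reproducibility

The test suite and the acceptance script run the end-to-end study at these
sizes, chosen as the package's desk-scale working point: 128×128 phantoms,
60 images, 20 epochs for the main run; a 12-image, 96×96 dataset for unit
tests; 1,000 randomized property cases per normalization/saliency
operator and 500 for the AP-versus-oracle check. A full training run takes
tens of seconds on one CPU core. Every stochastic step — phantom
rendering, dataset mixing, augmentation, negative sampling, shuffling,
bootstrap, randomization arms — is driven by explicit seeds, and
seed-identical calls are byte-identical.

One operationalization is worth stating plainly: "smoothed loss decreases
monotonically" is checked as a window-5 moving average being
non-increasing within a slack of 1% of the smoothed trace's range (and
ending at least 25% below its start). Per-image SGD produces per-epoch
means that can tick upward by a hair even on a healthy run; the slack
absorbs that noise without accepting a flat or rising trace.

## Known limitations

* The toy detector is a demonstration harness: two conv layers, one
  anchor scale, single-box images. Its absolute AP on phantoms (~0.2–0.4
  depending on seed) is not comparable to clinical-scale results and is
  not meant to be.
* The head classifies partly from box geometry; on phantoms this is the
  honest signal (the class *is* a function of position and bone width),
  but it means phantom classification accuracy says little about
  appearance-based classification on radiographs.
* `eq_region` and `table_consistent` disagree by construction; totals
  published elsewhere may follow either convention.
* The published augmented per-class totals follow no derivable rule from
  the stated ranges and are deliberately not reproduced.
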