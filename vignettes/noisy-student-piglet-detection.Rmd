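---
title: "Noisy-student detection of newborn piglets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noisy-student detection of newborn piglets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Monitoring farrowing (the birth process of a sow) with a ceiling camera
requires detecting newborn piglets reliably. Full-pen views make this hard:
piglets are small relative to the frame, frequently occluded by the sow, by
pen equipment or by each other, and recordings span day and night lighting.
Annotating enough frames by hand to train a robust detector is expensive.

`farrowdet` implements a semi-supervised *noisy student* pipeline built
around a geometric observation: births happen in a restricted area behind the
sow's rear. The pipeline is:

1. A **teacher** detector, trained on a modest set of manually annotated
   full-pen frames with four classes (*head*, *rear*, *tail*, *piglet*),
   is run over a large pool of unlabeled frames.
2. From the best head and rear detections the **restricted birth region** is
   derived: a circle on the head-to-rear axis, just behind the rear.
3. The square window bounding that circle is cropped and rescaled to a fixed
   size (640 x 640 by default), producing the **target image structure** in
   which the class space is reduced to *tail* and *piglet*.
4. Teacher detections with confidence strictly above a threshold (0.9)
   become **pseudo-labels** on the target images; an explicit review-queue
   hook mirrors manual verification, letting a user reject bad frames.
5. A **student** detector is trained on the pseudo-labeled target images
   under injected noise — a factor-four flip expansion, mixup blending at
   rate 0.5, and dropout (realized as random omission of training boxes) at
   rate 0.5.
6. Both models are evaluated with region-restricted Recall, Precision and F1
   from pooled TP/FP/FN counts (micro-averaging), against the *same*
   region-restricted ground truth.

## The birth region

With head center $h$, rear center $r$, $d = \lVert r-h \rVert$ and unit axis
$u = (r-h)/d$, the region is the circle with

$$ c = r + \alpha d\, u, \qquad \rho = \max(\beta d,\ \rho_{\min}), $$

and the crop window is the axis-aligned square of side $2\rho$ around $c$,
clipped to the image. Membership of a *box* in the region is decided by its
center point, with an inclusive boundary. Defaults are $\alpha = 0.15$,
$\beta = 0.45$, $\rho_\min = 16$ px: the circle sits just behind the rear
with a diameter comparable to the sow's hindquarters. No canonical magnitudes
exist for these fractions, so both are exposed in `region_params()` and all
geometric guarantees (rigid-motion equivariance, radius scaling) hold for
any values. When several head or rear detections compete, the
highest-confidence one wins, ties broken by larger area. Clipping happens
after the ideal square is computed, so edge-of-image regions yield non-square
pre-resize windows rather than padded ones.

The region is derived from the head and rear detections (not the tail): the
rear box is large and reliably detected, whereas the tail mark is the
smallest and least reliable class — using it as a geometric anchor would
make the crop window fragile exactly on the frames that matter. The
evaluation protocol uses the same head + rear derivation from the manual
annotations.

## The synthetic scene generator

No farrowing footage is distributed with this package; instead it ships a
seeded generator (`generate_scene()`, `generate_dataset()`) that emulates the
*structure* of the problem rather than its photometric appearance:

* a sow rendered as two overlapping filled ellipses (head lobe and a larger
  rear lobe) along a random axis, with a short dark tail mark at the rear
  apex;
* 0–14 piglets as small bright ellipses whose centers are sampled with
  strongly elevated density in a disc behind the rear (matching where births
  occur, and what makes the region transformation useful);
* partial occlusion: at rate `occlusion_rate` (default 0.3) a piglet is
  placed on the sow outline and drawn *below* it, or tucked under another
  piglet — its ground-truth box remains the tight bounds of the full rendered
  shape, matching the annotation practice of boxing partially visible
  animals;
* day/night illumination: day is full gain with sensor noise SD 5; night is
  gain 0.5, offset 4, noise SD 9. Farrowing recordings span day and night
  with varying lighting; this two-mode gain/offset/noise model is the
  package's own radiometric design;
* a smooth coarse floor texture (bilinearly upsampled Gaussian field,
  SD 6) and a 3 x 3 binomial optical blur before quantization to 8 bits.

Rendering intensities are fixed (floor 70, head lobe 140, rear lobe 180,
piglet 230, tail 25 before gain). They were calibrated once, during
development, so that each class is detectable and classifiable by a
classical segmentation detector — the stated purpose of the generator — with
class contrasts well above the texture amplitude but night-time
contrast-to-noise low enough that small objects genuinely suffer. Relative
piglet size is a parameter (`piglet_axis_range`, default 12–20 px body
length against a 260–340 px sow in a 640 px frame) rather than a constant,
since no canonical value exists.

What the generator does *not* emulate: pen equipment and rails, sow postures
other than lying, piglet articulation, motion blur, or video correlation
between frames. Passing the packaged benchmark therefore demonstrates that
the pipeline's *mechanics* (region derivation, remapping, filtering,
noising, evaluation) work end to end and that the scale/denoising advantages
of the target structure materialize — not that any particular accuracy will
transfer to real footage.

## The reference detector

Production deployments of this pipeline train a large neural detector;
that architecture is out of scope here and replaced by a contract (`detect_frame()`, `train`,
serialization) plus a CPU-scale reference implementation, so the pipeline is
trainable and measurable on one core. `train_config()` still carries the
conventional settings (300 epochs, batch 16, 640 input, learning rate 0.01)
for any gradient-trained backend plugged into the same seam.

The reference detector is a classical pipeline:

1. **Normalization.** Frames are denoised with a 3 x 3 binomial kernel and
   intensity-normalized against the pen floor: the 10% quantile estimates
   the floor level, and with a near-zero black level every object contrast
   scales with illumination gain, so day/night frames and sow-dominated
   target crops map to the same units. Upper-quantile anchors were rejected
   because they shift with the number of piglets in view.
2. **Intensity bands.** Training fits a robust (weighted-median) intensity
   center per annotated class, plus three background levels from non-box
   pixels (1-d Lloyd iterations with median updates). Several background
   levels matter in target crops, where most of the sow body is unannotated
   background.
3. **Segmentation.** Each pixel joins its nearest band; per class layer, a
   3 x 3 morphological opening removes speckle and blur rings, connected
   components are labeled (`EBImage::bwlabel`), and components below the
   class's minimum area are suppressed.
4. **Classification.** Each component is scored against per-class centroids
   of four blob features (log area, bounding-box elongation, median
   intensity, distance to the largest blob), standardized by pooled robust
   scales. Confidence is $\exp(-d^2/2\sigma^2)$ normalized over classes,
   with $\sigma$ the median within-class training distance (floored at 0.3);
   a single-class model falls back to the raw likelihood so its scores stay
   informative.

Three fitted quantities adapt the detector to its training scale:
per-class minimum areas (15% of the class's robust median blob area, never
below the configured 25 px speckle floor), the denoising bandwidth (more
smoothing passes for models trained on larger blobs, i.e. upscaled crops),
and the feature scales. Emitted boxes are the tight bounds of the segmented
component. Optical blur pulls that contour roughly a pixel inside the true
object edge — a deliberate property, not a defect: localization error that
is negligible for large blobs costs small objects dearly at an IoU-0.5
matching criterion, which is exactly the well-documented small-object
disadvantage that motivates cropping and upscaling the birth region.

Noise injection maps to this model as: mixup — training observations are
taken from blended frames with weights $(\lambda, 1-\lambda)$,
$\lambda \sim \mathrm{Beta}(1.5, 1.5)$, and the weighted-median centroid
estimation absorbs them without bias; dropout — each training box is
omitted with probability 0.5. Dropout here is a contract-level analogue of
fitting under perturbation, not an equivalence with network-internal
dropout. Mixup's "rate 0.5" is read as: each training sample is, with
probability 0.5, replaced by a blend of itself and another uniformly drawn
sample; connected components are disjoint by construction, so the reference
detector needs no non-maximum suppression.

## Why the student wins here

On the packaged benchmark the student's advantage over the teacher arises
from the transformation itself, mirroring the mechanism claimed for the
original pipeline at desk scale:

* **Scale.** The birth region (roughly 120–150 px) is resampled to
  640 x 640, so a piglet occupies ~20x more pixels in the student's view.
  Small or partially occluded piglets whose visible fragments fall below the
  teacher's minimum component area remain detectable for the student.
* **Localization.** Segmentation contours sit about a pixel inside the true
  object edge; at full-frame piglet sizes (12–20 px) that bias alone pushes
  many correct detections below the IoU-0.5 matching bar, while at crop
  scale it is negligible.
* **Noise.** Bilinear upsampling plus the student's wider fitted denoising
  bandwidth reduce effective sensor noise relative to object size, which
  matters most in night frames.
* **Possibility space.** With only tail and piglet classes (plus learned
  background modes), fewer confusable intensity bands compete during
  segmentation.

The evaluation keeps the comparison fair: the ground truth for both models
is the identical region-restricted set, and the same center-in-circle rule
is applied to both models' detections (the student's detections are mapped
back to source coordinates for the test, since the square crop contains
corners outside the circle).

## Evaluation protocol

`match_detections()` processes detections in decreasing confidence (ties:
larger area, then input order) and greedily matches each to the unmatched
same-class ground-truth box with the highest IoU at or above 0.5 —
matched = TP, unmatched detection = FP, unmatched ground truth = FN. There is no single canonical TP criterion; greedy confidence-ordered
matching at IoU 0.5 is the dominant convention, both knobs sit in
`eval_config()`, and the matching is validated against an exhaustive
optimal-assignment oracle on small instances (agreement ≥ 95%, count
invariants always). Whether cross-class matches should count is equally
unstated; class-aware matching is the default with `class_aware = FALSE` as
the alternative. Metrics follow the count definitions (Recall
$TP/(TP+FN)$, Precision $TP/(TP+FP)$, F1 $2TP/(2TP+FP+FN)$); pooled rows
micro-average the counts, never the per-class metrics; zero-denominator
metrics are reported as `NA`, never coerced. Reports are written as TSV
(3-decimal, rounded half away from zero) with a full-precision JSON
counterpart.

## The packaged benchmark and problem sizes

`benchmark_corpus()` fixes the study conditions the package's own results
refer to: 100 teacher training scenes, a 100-frame unlabeled pool (yielding
≥ 400 pseudo-labeled target crops after the factor-four flip expansion), and
100 evaluation scenes, all 640 x 640 with 1–12 piglets per scene, 30%
occlusion and mixed day/night lighting. `run_size_comparison()` re-trains
teacher and student on random subsets (50 and 100 images in the acceptance
configuration — a deliberate scale-down of the 100/250/500/1000
grid used in full-scale studies of this design) and evaluates both on the shared evaluation set; on this benchmark the
student's pooled F1 exceeds the teacher's at every size, reproducing the
direction, not the magnitudes, of the published comparison. Absolute
published values are not reproducible without the original footage and a
GPU-trained network.

Self-training over multiple generations is supported
(`pipeline_config(generations = k)`): the promoted student labels the next
generation's target crops, while the original 4-class teacher keeps
providing head/rear localization — a 2-class student cannot localize the
sow. The default student set is pseudo-labels only; the
`include_manual_in_student` flag adds the transformed manual annotations,
reflecting the generic description of student training on both.

## Degenerate inputs and numerical conventions

* Coincident head/rear centers raise a degenerate-pose error; frames where
  the teacher finds no head/rear pair are skipped and counted.
* "Above the 0.9 threshold" is read strictly (`>`), with a config flag for
  `>=`; float ties are measure-zero in practice.
* Boxes straddling the crop boundary are kept iff at least
  `retention_threshold` (default 0.5) of their area lies inside, then
  clipped; the evaluation remap uses a vanishing threshold so the
  denominator set is decided by the region rule alone.
* Images are quantized with round-half-to-even once per composite; box
  coordinates survive a YOLO write/read round trip within one step of the
  6-decimal serialized precision.
* All randomness flows from explicit seeds through a multiplicative
  child-seed deriver (kept below $2^{31}$); reruns of any pipeline stage
  with the same seed are bit-identical.

## Known limitations

The reference detector is intentionally simple: it cannot separate touching
piglets of the same intensity band (they merge into one component — also the
dominant real-world failure mode reported for full-pen monitoring), its
confidence is a class-posterior rather than a calibrated objectness, and its
accuracy figures are specific to the synthetic imaging model. The pipeline
layer, not the detector, is the contribution this package makes testable:
any stronger backend implementing the detector contract inherits the region
transformation, pseudo-label filtering, noising and evaluation unchanged.
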