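# farrowdet

Semi-supervised ("noisy student") detection of newborn piglets in farrowing
pens, for researchers in precision livestock farming and computer-vision
groups working on animal monitoring.

Detecting newborn piglets in full-pen camera views is hard: the animals are
small, frequently occluded by the sow or each other, and footage spans day
and night. Manual annotation at the scale a supervised detector needs is
expensive. `farrowdet` implements a self-training pipeline that converts a
modest manually annotated set into a much larger automatically annotated one
by exploiting where births happen:

1. a **teacher** detector trained on full-pen frames (classes *head*,
   *rear*, *tail*, *piglet*) localizes the sow's head and rear;
2. the **restricted birth region** is derived from them — with head center
   $h$, rear center $r$, $d = \lVert r - h\rVert$ and axis
   $u = (r - h)/d$, the region is the circle of center
   $c = r + \alpha d\,u$ and radius $\rho = \max(\beta d, \rho_{\min})$
   (defaults $\alpha = 0.15$, $\beta = 0.45$);
3. the square window bounding the circle is cropped and rescaled to
   640 × 640, classes are reduced to *tail* and *piglet*, and teacher
   detections with confidence **> 0.9** become **pseudo-labels**;
4. a **student** detector is trained on the pseudo-labeled crops under
   noise — flip expansion (×4), mixup (rate 0.5) and dropout (rate 0.5);
5. both models are scored region-restricted with
   $\mathrm{Recall} = \frac{TP}{TP+FN}$,
   $\mathrm{Precision} = \frac{TP}{TP+FP}$,
   $F_1 = \frac{2TP}{2TP+FP+FN}$, pooled counts micro-averaged, greedy
   IoU-0.5 matching.

Because no farrowing footage can be distributed, the package includes a
seeded synthetic farrowing-scene generator with pixel-accurate ground truth
(two-lobe sow, dark tail mark, 0–14 piglets clustered behind the rear,
partial occlusion, day/night illumination) and a CPU-scale trainable
reference detector (floor-normalized intensity bands → connected components
→ nearest-centroid classification) standing behind the same detector
contract a neural backend would implement. Everything — YOLO/LabelMe
annotation I/O, region geometry, crop/flip/mixup transforms,
confidence-filtered pseudo-labeling with a manual review hook, evaluation,
and the full pipeline — is exposed as ordinary R functions, with a thin CLI
in `inst/cli/farrowdet.R`.

## Worked example

Generate a small synthetic corpus, run one noisy-student generation, and
compare both models on the same evaluation scenes:

```r
library(farrowdet)

td <- tempfile(); dir.create(td)
corpus <- benchmark_corpus(td, master_seed = 1,
                           n_train = 30, n_unlabeled = 30, n_eval = 20)
cfg <- benchmark_config(corpus, file.path(td, "run"), master_seed = 1)
run <- run_noisy_student(cfg)
print(run)
```

```
  pseudo-labeled 30/30 frames (0 no region, 0 too few piglets)
noisy-student run
teacher (region-restricted):
  class TP FP FN recall precision    f1
   tail 15  5  5  0.750     0.750 0.750
 piglet 41 14 25  0.621     0.745 0.678
  Total 56 19 30  0.651     0.747 0.696
student generation 1:
  class TP FP FN recall precision    f1
   tail 20  4  0  1.000     0.833 0.909
 piglet 43 17 23  0.652     0.717 0.683
  Total 63 21 23  0.733     0.750 0.741
```

Reading the table: on the 20 evaluation scenes the teacher, restricted to
the birth region, recovers 65.1% of the tail/piglet ground truth (pooled
recall) at 74.7% precision (pooled F1 0.696). The student — trained purely
on the teacher's confidence-filtered pseudo-labels of 30 unlabeled frames,
flip-expanded and noised — raises pooled recall to 73.3% at equal precision
(F1 0.741). The gain concentrates where the transformation helps: small
objects that are marginal at full-frame scale (the tail row, and piglets
near the detector's minimum component area) are easy at crop scale. Models,
per-model reports (TSV + JSON) and a provenance log are written under the
run's output directory.

`run_size_comparison(cfg, sizes = c(50, 100))` repeats the comparison with
teacher and student trained on random subsets of their respective training
sets and tabulates pooled Recall/Precision/F1 per model and size
(`plot_size_comparison()` draws the accompanying line plot).

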