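# usjoint

Click-guided **joint segmentation and classification** of focal hepatic
lesions in B-mode ultrasound images, in R.

Characterizing focal liver lesions (cysts, hemangiomas, metastases,
hepatocellular carcinoma) on ultrasound is hard: speckle, low contrast and
overlapping phenotypes defeat fully automatic segmentation, and manual ROI
drawing is too slow for the clinic. `usjoint` implements the interactive
alternative: the user marks a lesion with a few clicks or a two-corner
bounding box, and one convolutional network — a shared encoder with a
segmentation decoder and a classification branch — simultaneously
delineates the lesion and predicts its type.

The core pieces:

* **Click encoding.** Foreground/background clicks become Euclidean
  distance maps \(D(p) = \min_c \lVert p - c \rVert_2\) (truncated at
  255); the network input is \((\text{image}, D_{fg}, D_{bg})/255\). With
  no background clicks, \(D_{bg} \equiv 255\).
* **Joint network.** (conv 3×3 → batch norm → ReLU) stages with 2×2 max
  pooling; the decoder restores resolution with fixed bilinear
  interpolation; the classification branch pools the deepest shared
  features (concatenated global average and max pooling) into fully
  connected layers.
* **Focal losses.** Pixelwise \(-(1-p_t)^\gamma\log p_t\) for
  segmentation, α-balanced \(-\alpha_y(1-p_y)^\gamma\log p_y\) for
  classification, trained on their sum with SGD (0.9 momentum,
  5×10⁻⁴ weight decay, halved-schedule learning rate).
* **Test modes.** *One-click*: a single in-lesion click. *Two-click*: a
  simulated bounding box converted to one center foreground click and
  four corner background clicks.
* **Evaluation.** Per-image Jaccard index, confusion matrix with
  per-class/overall accuracy, benign–malignant ROC with Youden-optimal
  operating point and bootstrap AUROC interval, one-vs-rest macro AUROC,
  paired sign-flip permutation comparisons.
* **Phantoms.** Because no public dataset accompanies the method, a
  simulator renders speckled B-mode-like images with four lesion
  phenotypes whose size distributions match the clinical means
  (16.8 / 17.4 / 26.2 / 23.3 mm), so the whole pipeline runs end to end
  on synthetic data. See `vignette("usjoint-methods")`.

## Worked example

A complete desk-scale study — 50 phantoms per class at 64² px, a joint
four-class network trained for 2,000 iterations, evaluated with five
simulated user inputs per test image in both modes (about 15 minutes on
one CPU core):

```r
library(usjoint)
res <- run_pipeline("demo_run", n_per_class = 50, image_size = 64,
                    pixel_spacing = 1, variant = "joint", n_classes = 4,
                    seed = 0)
res$reports$two_click
#> <usj_eval_report> joint variant, two_click mode, 200 predictions
#>   mean JI 47.2% +/- 29.9
#>   accuracy 92.5%
#>   benign/malignant AUROC 0.981 (sens 95.0%, spec 95.0% at Youden optimum)
#>   macro-average one-vs-rest AUROC 0.973
res$reports$one_click
#> <usj_eval_report> joint variant, one_click mode, 200 predictions
#>   mean JI 44.6% +/- 30.0
#>   accuracy 83.5%
#>   benign/malignant AUROC 0.988 (sens 99.0%, spec 88.0% at Youden optimum)
#>   macro-average one-vs-rest AUROC 0.959
```

Reading the numbers: each of the 40 held-out phantoms is segmented and
classified under 5 independent simulated user inputs (200 predictions).
The two-click mode — a jittered bounding box supplying one foreground and
four background clicks — localizes lesions better than a single click
(mean Jaccard overlap 47% vs 45%), and four-class accuracy is far above
the 25% chance level; the benign/malignant score
\(P(\text{metastasis}) + P(\text{HCC})\) separates the malignant phantoms
with AUROC ≈ 0.98. Phantom-scale numbers demonstrate that the pipeline
learns and is scored correctly; they are not clinical performance claims.

Individual stages are exposed as plain functions — `generate_phantom()`,
`simulate_foreground_clicks()`, `distance_map()`, `encode_input()`,
`simulate_bbox()`, `bbox_to_clicks()`, `build_network()`,
`train_network()`, `evaluate_system()`, `jaccard()`, `roc()`,
`youden_optimum()`, `compare_paired()` — with `tidy()`/`glance()` and
`autoplot()` methods on the result objects. A thin command-line wrapper
with `generate` / `encode` / `train` / `predict` / `evaluate` / `demo`
subcommands is installed at `inst/cli/usjoint.R`.

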