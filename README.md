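# periocrop

Oriented bounding-box tools for automated cropping of the eye (periocular)
region in full-face ocular-alignment photographs.

## The problem

Strabismus workups photograph patients in standardized gaze positions. Before
those photographs can be shared, archived, or fed to screening models, the eye
region has to be isolated — both to strip identifiable facial features and to
standardize the input. Two things make naive axis-aligned cropping inadequate:
patients tilt their heads, so the inter-eye axis is rarely horizontal, and
axis-aligned crops of tilted faces have inconsistent aspect ratios that
destroy image features on resize. The remedy is to detect the eye region as a
*rotated* bounding box — center `(cx, cy)`, side lengths `(w, h)`, angle `θ` —
and then rotate the crop so the inter-eye axis is horizontal.

`periocrop` implements the geometry, losses, evaluation protocol and clinical
quality gate this workflow needs, plus a procedural scene generator so the
whole detect → QA → crop → evaluate pipeline runs end to end with no trained
network:

- **Skew IOU** between rotated rectangles, computed exactly: the intersection
  polygon is assembled from edge–edge intersection points and contained
  vertices, sorted into a convex polygon, and fan-triangulated
  (`skew_iou()`), with an independent grid-sampling reference
  (`raster_iou()`).
- **ProbIoU regression loss**: each box becomes a Gaussian with mean
  `(cx, cy)` and covariance `R(θ) diag(w²/12, h²/12) R(θ)ᵀ`; the
  Bhattacharyya distance `B_D = B₁ + B₂` yields
  `ProbIoU = 1 − √(1 − e^{−B_D})` and the loss `L_Prob = 1 − ProbIoU ∈ [0,1]`
  (`prob_iou_loss()`).
- **Distribution focal loss** over `reg_max + 1 = 17` discrete offset bins:
  `L_DFL = −((y_{i+1} − y) log S_i + (y − y_i) log S_{i+1})`, with the
  expectation decoding `Σ i·S_i` (`dfl_loss()`, `decode_expectation()`).
- **Total regression loss** `L_total = 0.8·L_Prob + 0.2·L_DFL`
  (`total_loss()`); the task is single-class, regression-only.
- **Evaluation**: greedy confidence-descending matching, precision/recall,
  AP with monotone-envelope interpolation, mAP50 and mAP95 (mean AP over IOU
  thresholds 0.50–0.95 in steps of 0.05) via `map_range()`.
- **Preprocessing**: letterbox resize to 640×640 with exact box transforms
  (`letterbox()`), 4-image mosaic augmentation with affine box bookkeeping
  (`mosaic_augment()`), seeded stretch/blur/contrast augmentation
  (`random_photometric()`).
- **Deskewing crop** with user-adjustable margins (`deskew_crop()`) and the
  upload **QA gate**: ≥ 5 megapixels, eye-region area between 2.5% and 25% of
  the frame (a shooting-distance proxy), detection confidence ≥ 50%
  (`qa_gate()`).
- **I/O**: roLabelImg XML (`robndbox`) and normalized YOLO-OBB text, plus a
  `periocrop` command-line wrapper (`cli_main()`).

## Worked example

```r
library(periocrop)

sc  <- generate_scene(scene_spec(tilt = 8.5, area_fraction = 0.12, seed = 42))
det <- detect_eyes_baseline(sc$image)
det
#> <detection> conf 0.983 on 'img': rotated_box(480, 360, 542.864, 152.661, 0.148382)
skew_iou(det$box, sc$truth)
#> [1] 0.999

cfg <- default_config(); cfg$qa_min_megapixels <- 0.5  # synthetic-frame scale
qa_gate(c(ncol(sc$image), nrow(sc$image)), det, cfg)
#> <qa_report>
#>   resolution: 0.69 MP  [ok]
#>   eye-region area: 12.0%  [ok]
#>   confidence: 0.98  [ok]
#>   => ACCEPTED

deskew_crop(sc$image, det$box, margin_factor = 0.1)
#> <crop_result> 651x183  rotation applied -0.148 rad (-8.50 deg)  margin 0.10

map_range(list(det), list(sc$truth))
#> <eval_summary>
#>   precision: 1.000   recall: 1.000  (confidence cutoff 0.50)
#>   mAP50: 1.000   mAP95: 1.000
#>   ...
```

The scene was generated with an 8.5° head tilt; the baseline detector
recovers the eye-region box at IOU 0.999 with the correct angle (0.1484 rad),
the QA gate accepts the upload, and the deskewing crop applies −8.50° so the
inter-eye axis is horizontal in the 651×183 output (the box grown by 10% per
side). Detection scored against ground truth gives perfect precision, recall
and mAP on this one-image example.

The same pipeline is available from a shell:

```sh
periocrop synth --n 5 --seed 1 --out scenes/
periocrop detect --images scenes/ --out dets/
periocrop crop --image scenes/scene_0001.png --xml scenes/scene_0001.xml \
               --margin 0.1 --out crop.png
periocrop eval --det dets/ --truth scenes/ --size 960x720
```

## Vignette

`vignettes/periocrop-methods.Rmd` documents the model and its assumptions,
the numerical choices (tolerances, tie-breaks, boundary conventions), what
the synthetic scene generator does and does not emulate, and the package's
known limitations.
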