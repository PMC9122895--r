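---
title: "Counting overlapping C. elegans with multi-class detection"
author: "wormcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting overlapping C. elegans with multi-class detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcensus)
```

# The problem

Pond-style sensory assays drop tens of *Caenorhabditis elegans* (each about
1 mm long) into 5-mm agar wells and score the response by counting the worms
in each well. At these densities worms pile up. The arithmetic is
unforgiving: with pond area $\pi r^2 = 3.14 \times 2.5^2 = 19.625$ mm² and a
per-worm movement square of $0.7^2 = 0.49$ mm² (a fully extended 1-mm worm is
the diagonal of a 0.7-mm square), only about
$\lfloor 19.625 / 0.49 \rfloor = 40$ worms fit without touching. Dropping up
to 100 worms therefore forces overlaps of roughly
$\lceil 100 / 40 \rceil = 3$ animals, and a detector must expect overlap
groups of up to about 4. `classDesign()` reproduces this arithmetic.

One-stage object detectors post-process their anchor-box proposals with
confidence filtering and non-maximum suppression (NMS). NMS removes, per
class, every box whose intersection-over-union (IoU) with a stronger box
exceeds a threshold. For well-separated worms that is exactly right; for a
pile of 3 worms the three correct boxes overlap heavily, NMS keeps one, and
the count is short by two. This failure is *structural*: it happens after
the network, so a better backbone cannot fix it.

The multi-class counting scheme (MCC) sidesteps it without touching the
detector: a group of $n$ overlapped worms ($n = 1\ldots4$) is labelled class
$n$. Since NMS runs per class, a class-3 box never suppresses a neighbouring
class-1 box. At evaluation time each class-$n$ detection is **divided** into
$n$ unit detections (`divideClasses()`), putting one-class (OCC) and
multi-class counts on the same per-worm scale.

# What the package implements

* **Pre-processing** (`preprocessPipeline()`): grayscale + bilinear resize to
  704 x 528; background estimation by grayscale closing with a disc
  (default diameter 25 px, the midpoint of the 20-30 px worm-scale band)
  followed by a 3 x 3 median filter; difference-of-Gaussians rim emphasis
  (kernel sizes 20 and 30, $\sigma = (k-1)/6$); circle Hough detection of
  the pond rim; pixelwise division of image by background, with the mean
  ratio over the border strips (20 px) filling everything outside the pond.
* **Scene synthesis** (`makeWormShape()`, `composeClassImage()`,
  `makeScene()`, `makeDataset()`): procedural worm bodies, overlap-group
  composites, full simulated fields with ground truth in both conventions,
  and Darknet-TXT/JSON export.
* **Detection machinery** (`boxIoU()`, `confidenceFilter()`, `nms()`,
  `ciouLoss()`, `headFilterCount()`, `simulateDetector()`).
* **Evaluation** (`divideClasses()`, `matchAndCount()`, `prCurve()`,
  `averagePrecision()`, `summarizeErrors()`, `runExperiment()`).

Training a YOLO network is deliberately out of scope; the architecture the
synthetic data targets is documented in
`system.file("extdata", "yolov4_reference.yaml", package = "wormcensus")`
but never instantiated. Every claim the package tests is independent of the
network weights: it is a property of the post-processing and of the counting
scheme.

# The synthetic scene generator

No public image set accompanies the counting problem, so the generator is a
first-class module, not a fixture. It emulates the statistical structure the
method depends on — elongated, curved, dark objects on a flat bright
background, composed into overlap groups — rather than worm photorealism.

A worm body is an arclength-parameterised heading profile
$\theta(s)$ integrated into a skeleton polyline, with three posture modes
matching the classic locomotion taxonomy:

* **wave**: sinusoidal heading, amplitude 0.5-1.1 rad, 1-2.2 body waves;
* **omega**: a 1.2-1.7 $\pi$ total turn (open, like the letter Ω);
* **coil**: a 2.4-3.2 $\pi$ turn with a radial wobble, which guarantees a
  self-crossing (asserted per draw, resampling the wobble if needed).

Defaults: arclength 50-90 px and mid-body half-width 1.8-2.8 px (about 1 mm
x 50-80 µm at the roughly 90 px/mm working scale), tapered toward head and
tail; darkness 0.35-0.6 below the background of 1.0, which matches the
appearance of a divided (background-corrected) image; additive Gaussian
noise with $\sigma = 0.02$.

A class-$n$ model image (default 100 x 100 px) samples $n$ shapes with
replacement, rotates them uniformly over 0-360°, zooms by 0.8-1.2 (worm
stage is not controlled for, so mild scale variation), and offsets them with
$\sigma = 6$ px until every worm's tight box shares at least 1 px² with
another worm's box — the operational definition of an overlap group. Groups
are compact by construction, so the boxes of co-grouped worms typically
exceed the 0.45 NMS threshold against each other, which is precisely the
regime in which one-class counting fails.

A scene draws $N \sim \mathcal{U}\{10, \ldots, 80\}$ groups (class mix
uniform over 1..4 by default; both are configurable because the source
balance is not knowable), places them uniformly at random subject to
*groups not overlapping each other* — overlap happens only inside groups,
keeping class labels well defined — and records per-worm and per-group
ground truth. Worm count conservation
($\sum_g \mathrm{class}_g = |\mathrm{units}|$) is a class invariant, checked
by validity. With `pond = TRUE` the field instead mimics a raw photograph:
a pond disk with a dark rim, a left-right illumination ramp and a darker
outside region, which lets the pre-processing chain be tested end to end
against known geometry.

What the generator does **not** model: worm texture and translucency,
body-contact deformation, motion blur, debris, meniscus shadows, and
overlaps *between* groups. Tests passing on synthetic scenes therefore
validate the counting logic and the post-processing chain, not real-image
detection accuracy; the headline metrics of a trained detector on real
micrographs are out of reach by design.

# The simulated detector

`simulateDetector()` replaces the trained network with an error model so the
post-processing chain acts on realistic inputs. Per true object (unit box in
OCC mode, group box in MCC mode) it emits $K = 2$ candidate boxes with
positional jitter ($\sigma = 2$ px, size jitter at half that), confidences
drawn from Beta(8, 2) (mean 0.8), misses objects with probability 0.02 and
adds Poisson false proposals at 0.02 per true object with confidences
uniform on [0.05, 0.6]. Candidates then pass `confidenceFilter()` at 0.30
and per-class `nms()` at 0.45. With jitter, miss and false rates at zero and
$K = 1$ the detector is perfect up to NMS, which the tests use as an
identity check.

The undercounting mechanism needs no tuning to appear: it is geometric.
Co-grouped worms have heavily overlapping boxes, so their class-1 candidates
suppress each other in OCC mode, while in MCC mode the group survives as one
class-$n$ detection whose division restores the count.

# Evaluation choices

* **Matching**: greedy, confidence-descending, one-to-one at IoU ≥ 0.5
  (PASCAL-style). The matching threshold is configurable; 0.5 is the
  convention for this problem.
* **MCC crediting**: divided unit detections share one box, so unit-level
  IoU matching would be ill-posed. Detections are matched at group level; a
  class-$n$ detection on an $m$-worm group credits $\min(n,m)$ TP,
  $\max(0, n-m)$ FP and $\max(0, m-n)$ FN. A worm that exists but is not
  claimed is a false *negative* (it is missing from the count), even though
  a detector-centric reading might call the under-claiming box a false
  positive; recall is only meaningful under the former.
* **Empty denominators**: precision := 1 when TP+FP = 0, recall := 1 when
  TP+FN = 0, F1 := 0 when p + r = 0 (vacuous-truth convention, needed for
  edge cases in sweeps).
* **AP**: the literal step sum
  $\sum_k (R_k - R_{k-1}) P_k$ with $R_{-1} = 0$ over the distinct
  confidence cutoffs, no 11-point or all-point interpolation. A brute-force
  cutoff-enumeration oracle in the test suite checks it.
* **Detection error**: detections minus ground truth per image (after
  division in MCC mode); summaries use the sample (n-1) standard deviation
  and unit-width histograms.
* **NMS details**: suppression on IoU *strictly above* the threshold, except
  that exact duplicates (IoU = 1) are always suppressed; ties in confidence
  break by smaller x, then smaller y, then input order, making every result
  deterministic.
* **DoG orientation**: the difference is computed small-minus-large, with a
  flag for the opposite sign; the Hough stage votes on the magnitude, so the
  choice is inconsequential downstream.
* **Division safety**: the background estimate is floored at 1/255 before
  division; the periphery used for the outside-pond fill is the four border
  strips (20 px) minus any in-pond pixels.

# The comparison experiment

```r
report <- runExperiment(experimentConfig(seed = 1))
report
```

`experimentConfig()` defaults define the benchmark regime: 20 scenes of
704 x 528 px, 14-20 groups per scene with class mix (0.05, 0.15, 0.40,
0.40) — an overlap-rich crowd of roughly 40-70 worms per field, the regime
the class-design arithmetic predicts for full load. One global seed fans out
to fixed per-stage offsets (library, scenes, per-mode detector runs), so the
whole report is byte-reproducible. These sizes keep a full run around a
minute on a laptop core while leaving the OCC/MCC contrast unambiguous; the
test suite asserts the *orderings* (MCC recall above OCC recall, OCC error
negative and deepening with crowding), not specific simulated magnitudes,
because magnitudes are properties of the error model, not of the method.

# Known limitations

* The circle Hough search assumes one pond per image; multi-well frames
  must be cropped first.
* Procedural worms approximate posture statistics; they carry no intensity
  texture, so segmentation-style methods would find these scenes easier
  than real data. Detection-side conclusions transfer; pixel-level ones may
  not.
* Class labels stop at 4 (configurable ceiling, untested beyond 4); piles
  of 5+ worms would be divided as 4 + 1 by a real detector, as observed in
  crowded wells.
* The NPY sidecar writer supports exactly the float64 C-order subset the
  package emits.
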