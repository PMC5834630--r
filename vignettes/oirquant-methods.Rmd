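---
title: "Automated scoring of oxygen-induced retinopathy flat mounts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of oxygen-induced retinopathy flat mounts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oirquant)
```

## The problem

In the mouse oxygen-induced retinopathy (OIR) model, pups exposed to
hyperoxia lose central retinal vessels; on return to room air the hypoxic
retina regrows vasculature and develops pathological preretinal
neovascularisations ("tufts"). Severity is scored on lectin-stained flat
mounts by three readouts: tuft area, vascular network density, and the size
of the avascular (vaso-obliterated) central zone. Manual scoring is slow and
carries large inter-observer error; `oirquant` computes all three readouts
automatically, with every size parameter expressed as a fraction of the
flat-mount diameter $\Phi$ so the same configuration applies across
magnifications.

## Pipeline model

1. **Geometry.** The mosaic is smoothed with a Gaussian of standard
   deviation 2.5% of the image size (we interpret "image size" as
   $\max(\mathrm{rows}, \mathrm{cols})$; configurable); the binarisation
   threshold is the histogram valley between the two highest peaks (256
   bins; valley ties resolved toward lower intensity, which favours larger
   masks and is recoverable by an explicit threshold override). After hole
   filling, the largest 8-connected object is the retina.
   $\Phi$ is defined as the *equivalent-circle diameter*
   $2\sqrt{A/\pi}$ of that mask — the flat-mount outline is petal-lobed by
   dissection, so a bounding-circle definition would be biased upward. The
   optic-nerve centre defaults to the mask centroid and can be overridden;
   content-based nerve-head detection is out of scope.

2. **Local background.** Intensities are rescaled so the bottom and top 1%
   of pixels saturate; values are quantised to 10 levels; 8-connected
   constant plateaus all of whose neighbours are brighter are regional
   minima, weighted by plateau area. The background mean $I_b$ and spread
   $\sigma_b$ at a pixel are the weighted statistics of minima values inside
   a circular window of diameter $0.07\,\Phi$, with one refinement pass that
   excludes values beyond $3\sigma_b$; windows without minima are filled by
   bicubic interpolation. The validation threshold is $I_b + 3\sigma_b$.
   Two details are worth making explicit. Minima detection is *mask-aware*:
   pixels outside the retina are ignored, because the dark surround would
   otherwise be the only regional minimum and the model would collapse to
   the off-tissue level. And the estimate is defined by inter-vessel
   background pockets; on degenerate inputs without local minima (a pure
   monotone ramp, say) the model falls back to global statistics with a
   warning — tracking an illumination field requires minima spread across
   the tissue, which real vascularised retinas provide.
   For speed the windowed statistics are evaluated on a decimated grid
   (every 8th pixel by default) and upsampled with Catmull–Rom bicubic
   interpolation; `decimate = 1` gives the exact per-pixel computation, and
   the suite checks the decimated field against the exact one.

3. **Tile features.** Tiles of side $0.01\,\Phi$ carry five descriptors
   computed from the half-pixel-smoothed image: local contrast
   $I_{loc}$ (ratio to the moving average over a square window of side
   $\Phi/8$), global contrast $I_g$ (affine map onto $[0,1]$), a
   Laplacian-of-Gaussian response at scale $\Phi/60$ (negated so bright
   blob-like structures respond positively, negatives clipped, globally
   normalised — the discrete truncated kernel is re-centred to exact zero
   sum so structure-free images respond exactly zero), and the fractions of
   rotation-invariant uniform local binary pattern codes 0 (homogeneous)
   and 9 (irregular, non-edge texture). LBP uses $P = 8$ circle samples by
   bilinear interpolation; the radius $R$ (default 1 px) and difference
   threshold $U$ (default 0.01 of the rescaled range; $U = 0$ is textbook
   LBP) are not fixed by the method description and are configurable.

4. **Tuft classification.** Tiles inside the $0.2\Phi$–$0.8\Phi$ annulus
   around the optic nerve are classified by quadratic discriminant
   analysis: per-class Gaussian densities with empirical priors, decisions
   by expected-cost minimisation under 0/1 cost (ties resolved toward
   "normal", the conservative choice). Densities are evaluated in log space
   via Cholesky factors; singular covariances receive a ridge of
   $10^{-6}\,\mathrm{tr}(\Sigma)/5$. For training, a tile is diseased when
   *strictly more than* 25% of its pixels lie in the annotator consensus
   (at least 4 of 6 evaluators). Predicted tiles are validated by
   thickness: a pixel survives only if the fraction of pixels above
   $I_b + 3\sigma_b$ in a square neighbourhood of side $0.01\,\Phi$
   *strictly exceeds* 80%. A thin bright vessel fills only a narrow band of
   any neighbourhood and is discarded; this step requires the neighbourhood
   to be meaningfully wider than a vessel, which holds at the method's
   working geometry (vessels of ~5 px on a mount of ~3000 px).

5. **Vasculature.** Vessels are binarised by adaptive mean (Bradley)
   thresholding with window $\Phi/50$ via an integral image. Two
   implementation choices matter. First, the sensitivity default is 1.15 —
   foreground must exceed the local mean by 15%, the offset of the original
   adaptive-mean method with polarity flipped for bright-on-dark
   fluorescence. A pure mean comparison (sensitivity 1) marks roughly half
   of all noise pixels foreground, which is above the 8-connected
   percolation threshold: noise then forms giant connected components that
   no speck filter can remove. Second, the image is pre-smoothed with the
   same half-pixel Gaussian the feature stage defines; this lifts the noise
   margin without displacing vessel boundaries at the working resolution.
   Objects under 25 px are removed, the mask is thinned (Guo–Hall), spurs
   shorter than $0.005\,\Phi$ are pruned, and branch points are skeleton
   pixels with three or more skeleton neighbours, 8-adjacent branch pixels
   merged to their rounded centroid. Total length counts 1 per axial and
   $\sqrt 2$ per diagonal adjacent skeleton pair. Branch counts are
   reported after pruning; `prune_frac = 0` restores the raw skeleton.

6. **Avascular zones.** The skeleton indicator is blurred with a Gaussian
   of $\Phi/250$, binarised with a Bradley threshold (window $\Phi/50$,
   sensitivity 1, as specified for this stage), and 8-connected background
   objects inside the central $0.6\,\Phi$ disk are kept when their maximum
   Euclidean distance to the nearest *original* skeleton pixel strictly
   exceeds $0.01\,\Phi$. Far from any vessel the blurred field is pure FFT
   round-off, so values below $10^{-9}$ of the field maximum are floored to
   exact zero before the strict comparison — otherwise vessel-free regions
   binarise as numerical speckle. The unspecified "morphological cleanup"
   is a closing with a disk of radius $0.005\,\Phi$ followed by an opening
   of $0.0025\,\Phi$: it smooths contours without creating or destroying
   objects at the scale of the region of interest. Objects touching the ROI
   border are kept (the central ischemic zone touches nothing else).

## The covariance denominator

The method's printed covariance estimator divides each class's centred
scatter by $N - 1$, the *total* observation count. Implemented literally,
this deflates the minority (tuft) class covariance by the class-imbalance
factor — roughly 25× on tile data — and collapses its density to a needle
around the class mean: on synthetic fixtures, tiles whose features matched
the tuft training mean were still classified "normal" (recall near 30%,
zero false positives), which no published use of the method exhibits. We
therefore default to the per-class denominator $N_k - 1$
(`cov_mode = "per_class"`), the standard unbiased estimate, and keep the
literal form available as `cov_mode = "total"`.

## The synthetic-data generator

`generate_retina()` produces flat-mount-like images with *exact* ground
truth; realism is secondary to exactness, because every acceptance check
derives its expected value from the generator record.

* **Retina**: a lobed disk (four petal lobes, 5% amplitude) whose area
  matches a circle of the requested $\Phi$; default $\Phi$ of 512 px for
  vessel-tree and screening scenarios, 768 px where the tuft thickness
  validation needs vessels thinner than the $0.01\,\Phi$ neighbourhood,
  and 1024 px for avascular scenarios. These reduced scales keep a full
  fixture suite affordable while preserving the size ordering the method
  assumes (vessel width well below the Bradley window and the validation
  neighbourhood).
* **Vessel tree**: six first-order vessels leave a ring around the centre
  and branch recursively (default 3 generations, segment length decaying by
  0.78, width tapering from 5 to 3 px, midpoint-displaced for mild
  tortuosity). Drawing is collision-staged: a stroke is committed only
  while it stays inside a safety margin eroded from the retina outline and
  clear of previously drawn vessels (beyond a start exclusion where
  children legitimately merge with their parent); a child that cannot be
  drawn is dropped and its parent node is recorded as a branch point only
  if two children actually drew. The drawn topology therefore always
  equals the recorded one — the property the exact branch-count checks
  rest on.
* **Capillary mesh and avascular discs**: scenarios with vessel-free discs
  add a square capillary lattice (spacing 1.2% $\Phi$, within the
  biological inter-capillary range) and bound each disc with three
  concentric capillary rings — emulating the dense vascular front that
  borders real OIR vaso-obliterated zones. Without such a front the blurred
  skeleton has no closed foreground ring around the zone and background
  tendrils merge with it; a uniform sparse lattice right up to the rim is
  the pathological case, not the biological one.
* **Tufts**: clusters of overlapping bright discs (radius 1.2–2.2% $\Phi$)
  with multiplicative speckle texture at ~2 px scale, placed in the
  mid-periphery away from vessel-free zones.
* **Signal model**: background 0.15, vessels +0.55, tufts ~0.75 with
  ±40% speckle, multiplied by a smooth illumination field (random-direction
  ramp plus vignette, 15% amplitude), plus Gaussian noise of SD 0.02, with
  optional saturation clipping and photobleached patches as stress options.
  All randomness derives from one named seed; identical seed and parameters
  give bit-identical output.

What the generator does **not** emulate: stitching seams, microglial
staining, out-of-focus blur, true capillary network topology, or the
diversity of real tuft morphologies. Passing tests therefore demonstrate
the correctness and internal consistency of the implementation under
controlled conditions, not clinical-grade accuracy on real mosaics — the
published evaluation against human annotators cannot be reproduced without
the original image sets.

## Numerical choices and degenerate inputs

* Strict inequalities at printed boundaries are preserved exactly: a tile
  at exactly 25% consensus is normal, a validation fraction of exactly 80%
  is rejected, an object at max distance exactly 1% $\Phi$ is rejected, a
  pixel marked by exactly 4 of 6 annotators is consensus.
* Integral-image box means are computed on the mean-centred image so
  constant regions compare exactly equal to their local mean (strict
  comparisons cannot flip on accumulation round-off).
* Constant images: the saturating rescale returns 0.5 everywhere; global
  contrast normalisation raises an error (no contrast to normalise);
  delineation raises a no-histogram-valley error.
* A constant-background window sees a single minima value, so
  $\sigma_b = 0$ and the threshold equals $I_b$ there.
* The tie rule in classification, the valley tie rule in delineation, and
  the "normal"-preference order are all deterministic, so identical inputs
  give identical outputs; the pipeline contains no hidden randomness
  (seeds appear only in the generator and in random tile selection).

## Problem sizes used by the test and acceptance suites

Branch-count recovery uses 20 noise-free tree fixtures at $\Phi = 512$
(3–6 trunks, 2–3 branching generations, 9–42 planted branch points).
Avascular recovery uses 8 mesh fixtures at $\Phi = 1024$ with disc radii
3–6% $\Phi$. Tuft-area correlation uses 20 fixtures at $\Phi = 768$ with
1–10 planted tuft clusters, evaluated by the two-fold
(train-on-half, swap) protocol. These sizes are the package's reference
study conditions; they were chosen once, for the geometric reasons above.

## Cross-image generalisation of the tuft classifier

The tile features and tuft labelling are essentially exact — across
synthetic fixtures the planted tuft area and the area of QDA-positive tiles
under oracle labels correlate almost perfectly — and a classifier trained
and applied on the *same* image misclassifies at most ~1% of tiles. The
hard step is generalising across images: the method's global
normalisations (the 1% saturating rescale, whose upper cut depends on how
much bright tuft area an image contains, and the global $[0,1]$
normalisations of $I_g$ and $I_{LoG}$) shift feature scales from image to
image, so a classifier trained on pooled tiles from one image set produces
a small but roughly constant rate of bright-vessel false positives on new
images, a portion of which survives thickness validation where they
coincide with bright background texture. The same behaviour is visible in
the method's published evaluation (validation-step rationale and large
relative errors against consensus). Under the package's reference
conditions the planted-vs-measured tuft-area correlation across fixtures
therefore falls well short of the near-perfect tile-level agreement, and
the corresponding end-to-end check in the validation suite currently
fails; `scripts/acceptance.R` reports the measured correlation. The
branch-count and avascular-area recoveries, which involve no cross-image
training, are tight.

## Known limitations

* $\Phi$ must be large enough that $0.01\,\Phi$ is at least 3 px; the
  pipeline refuses smaller tiles.
* The thickness validation loses its discriminative power when vessels are
  as wide as $0.01\,\Phi$; such images are outside the method's intended
  geometry.
* The avascular criterion is geometric, not physiological; zones bounded by
  sparse, dim vasculature inherit the segmentation's errors.
* Training requires at least two tiles per class inside the annulus;
  training sets without any diseased tiles cannot fit a classifier.
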