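---
title: "EagleSeg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EagleSeg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EagleSeg)
```

EagleSeg segments 8-bit grayscale images in two phases: a histogram-based
multilevel threshold search, followed by a morphological chain that isolates
a single bright compact region (the intended use case is a contrast-enhanced
tumor in a T1 MRI slice). This vignette records the model, the parameters
that matter, and the design decisions taken where the procedure left choices
open.

## Phase one: Kapur-entropy multilevel thresholding

Given the normalized 256-bin histogram $p_0,\dots,p_{255}$ of an image,
a set of $k$ thresholds $t_1 \le \dots \le t_k$ partitions the gray range
into $k+1$ classes $[0,t_1], (t_1,t_2], \dots, (t_k,255]$. The objective is
Kapur's entropy

$$F(t) = \sum_{i=0}^{k} H_i, \qquad
  H_i = -\sum_{j \in \mathrm{class}_i} \frac{p_j}{A_i}\ln\frac{p_j}{A_i},$$

with $A_i$ the probability mass of class $i$. Conventions frozen throughout
the package: natural logarithm; $0\ln 0 := 0$; classes with $A_i = 0$
contribute nothing; a threshold belongs to its lower class; duplicated
thresholds produce empty classes. The duplicate-and-endpoint conventions
matter because optimal threshold vectors for real images routinely contain
repeats and the endpoints 0 and 255, and the fitness must remain
well-defined there.

`kapurFitness()` evaluates $F$ from two prefix-sum tables in $O(k)$ per
call; tests compare it against a naive double loop at `1e-10`.
`exhaustiveOptimum()` enumerates all non-decreasing $k$-tuples
(lexicographically, ties broken toward the smallest tuple) and is the
ground-truth oracle for $k \le 2$; it refuses instances above a configurable
candidate-count limit (default 250,000) rather than silently running for
hours.

### The optimizer

`runDOBES()` maximizes $F$ with a bald eagle search over continuous
positions in $[0,255]^k$. Each of $N$ agents $P_i$ moves through three
phases per iteration:

* **select** (exploration): $P_i' = P_{best} + \alpha r (P_{mean} - P_i)$,
  one uniform draw $r$ per agent, $\alpha$ = 2 by default (admissible range
  1.5–2).
* **search** (spiral exploitation):
  $P_i' = P_i + m_i (P_i - P_{i+1}) + l_i (P_i - P_{mean})$ with spiral
  coordinates $lr_i = r_i\sin\theta_i$, $mr_i = r_i\cos\theta_i$,
  $\theta_i = \alpha_s \pi u_i$, $r_i = \theta_i + R v_i$
  ($\alpha_s$ = 10 in 5–10, $R$ = 1.5 in 0.5–2).
* **swoop** (dive):
  $P_i' = u P_{best} + l1_i (P_i - c_1 P_{mean}) + m1_i (P_i - c_2 P_{best})$
  with hyperbolic coordinates ($\sinh/\cosh$, $r_i = \theta_i$) and
  $c_1 = c_2 = 2$ in 1–2.

Dynamic opposition learning (DOL) enters twice. At initialization the $2N$
union of a random population and its dynamic opposites
$x_{do} = x + w\,r_1 (r_2 (\ell + h - x) - x)$ (per-dimension draws, weight
$w = 3$, clipped to bounds) is evaluated and the fittest $N$ agents are
kept, so the starting population is never worse than plain random. Inside
the search phase each candidate is evaluated together with its dynamic
opposite and the agent adopts the fittest of {current, candidate, opposite}.
`runBES()` disables both (plain random initialization, plain greedy
candidate acceptance) and serves as the ablation baseline.

Design choices where the procedure was open, all frozen for
reproducibility:

* Greedy per-agent acceptance in **all three** phases. Greedy acceptance is
  mandatory in search and swoop for a monotone convergence curve; the
  original search method also accepts select-phase candidates greedily, and
  doing so preserves every stated contract, so the select phase is greedy
  too.
* The spiral neighbour index wraps: agent $N{-}1$ pairs with agent 0.
* Spiral normalizers $\max(lr)$, $\max(mr)$ are maxima of **absolute**
  values with a zero-max guard (raw $\sinh/\cosh$ coordinates can be
  negative or huge, and the plain maximum would be ill-defined).
* Phase randomness ($r$, $u$) is one scalar draw per agent; the DOL draws
  $r_1, r_2$ are per dimension.
* Positions stay continuous; each fitness evaluation repairs the position by
  clipping to $[0,255]$, rounding half-up and sorting (duplicates kept).
  Round-half-up rather than R's banker's rounding keeps results bit-exact
  across platforms.
* Rerun $j$ seeds the RNG with `seed + j - 1`, so the 10-rerun protocol is
  reproducible and individually re-runnable.

The default budget is the reference protocol: $N = 30$ agents, 100
iterations, 10 reruns. The convergence slot records the best-so-far fitness
per iteration of the best rerun and is non-decreasing by construction.

### Known behavior of the objective

Kapur's entropy is degenerate on spiky histograms. A class holding a single
point mass has zero entropy, so for a noise-free histogram supported on a
few exact values the global optimum *groups* all spikes into one class
(duplicated thresholds) rather than separating them — the two-spike
landscape's optimum is $\ln 2$ with both spikes together, and the package's
brute-force oracle confirms this. Consequences:

* The pipeline needs within-class spread (noise, texture) to behave as a
  segmenter. The phantom generator's default noise sigma is 5 gray levels
  partly for this reason; at sigma exactly 0 threshold placement is
  arbitrary-to-degenerate and no separation guarantee exists.
* Classes of vanishing-but-nonzero mass contribute full normalized entropy
  at no cost. Histograms of real images have exact zeros outside their
  support, so `makeMixtureHistogram()` truncates densities below `1e-12` to
  zero; without this a discretized Gaussian mixture rewards thresholds
  placed inside its unphysical far tails.
* Under strongly unbalanced class masses the optimum drifts toward the
  heavy modes (boundaries settle 1.5–2 sigma from a heavy mode rather than
  at valley midpoints). This is a property of the objective, not of the
  optimizer, and it shapes both the phantom geometry (below) and what one
  should expect on real images.

## Phase two: threshold image, binary mask, morphology

`quantizeImage()` renders the "threshold image": each pixel is replaced by
its class representative — by default the round-half-up intensity-weighted
class mean, which minimizes MSE against the input among per-class constants
(`class_floor` is available for visual parity with typical level plots;
empty classes fall back to their interval midpoint). `binarizeImage()`
marks a configurable set of class indices as foreground; the default is the
brightest class alone, matching a bright target on a darker background —
this is an inference from the use case, not a prescription, hence the
argument.

`postprocessMask()` then applies, in order: Canny edge detection on the 0/1
raster (Gaussian sigma 1.0, hysteresis thresholds 0.1/0.2 relative to the
maximum gradient magnitude), dilation by a Euclidean disc (radius 2),
small-component removal (default threshold 1% of the image area),
hole-filling, and largest-component selection. The chain reconstructs a
solid blob from its dilated closed edge loop while speck edges stay below
the area threshold. None of these numeric parameters is canonical; all are
exposed in `morphControl()`. Further conventions:

* Foreground components use 8-connectivity by default (configurable to 4);
  the hole-filling flood fill uses 4-connectivity on the background — the
  standard duality that avoids topological paradoxes.
* Component labels are assigned in row-major raster order of each
  component's first pixel, which makes the "largest component" tie-break
  deterministic.
* Canny on an exactly constant mask must return no edges; gradient
  magnitudes below `1e-6` (FFT round-off, far below the order-1 magnitude
  of a genuine 0/1 step) are treated as zero.
* An empty input mask propagates to an empty output with a warning rather
  than an error: downstream rerun loops should not die on a degenerate
  threshold draw.
* The recovered region is the blob grown by roughly the dilation radius
  (the chain has no matching erosion), so overlap scores saturate around
  0.93–0.95 rather than 1.0 for disc-like targets of radius 30–40 px. This
  bias is visible and deliberate: the chain follows the stated order of
  operations.

Dilation and the 2-D convolutions inside Canny/SSIM are delegated to
EBImage; labelling, hole filling, boundary tracing (Moore radial sweep) and
Canny's suppression/hysteresis logic are implemented here because they need
the package's connectivity conventions. Every one of these stages is tested
against an independent naive implementation (pairwise-distance dilation,
stack flood fill, double-loop entropy) on random rasters.

## Quality metrics

`imgMSE`, `imgPSNR` (peak 255, `Inf` sentinel at zero error), `imgSSIM`
(canonical 11×11 Gaussian window, sigma 1.5, $K_1 = 0.01$, $K_2 = 0.03$,
$L = 255$; valid-window averaging, so images must be at least 11×11) and
`diceCoef` (two empty masks give 1). Rerun summaries use the population
standard deviation (divide by $n$), frozen for determinism. MSE/PSNR pairs
published for this family of methods are sometimes mutually inconsistent
(a $10^3$-scale MSE implies a PSNR tens of dB below the printed value), so
reconstruction quality is validated by properties (identity, symmetry,
monotonicity, closed forms on constant images) rather than against printed
table cells.

## The phantom generator

`makePhantom()` renders the study conditions for every end-to-end test: a
256×256 piecewise-constant image with class means 20/90/160/230, a small
bright central disc (radius 10% of the image side) as the brightest
background structure, a broad mid-gray band carrying one bright tumor disc
(radius 34 px, area ≈ 3,600 px) plus five 3-pixel bright specks, and
additive Gaussian noise (default sigma 5, clipped to [0,255], rounded
half-up). The geometry is deliberate:

* The tumor sits in the mid-gray band, far below the top threshold, so its
  surroundings contribute no near-threshold pixels.
* The brightest background band is kept small (≈ 2,100 px). Kapur's
  optimum places the top threshold 1.5–2 sigma above that band's mean, so a
  fraction of its noise tail always crosses the threshold; a small band
  bounds the stray field so that even fully merged it cannot out-grow the
  tumor component under largest-component selection.
* Specks test small-region removal; the noise-free histogram support is
  exactly the class means, which pins the histogram code.

What the phantom does **not** emulate: MRI physics (bias fields, partial
volume, Rician noise), anatomical shape variability, and histogram valleys
filled by texture. Passing the phantom suite therefore demonstrates the
pipeline's mechanics — threshold placement on a multi-modal histogram,
stray suppression, blob recovery — not clinical performance.

## Statistical checks and problem sizes

The test suite validates, among others: the analytic uniform-histogram
optimum ($t = 127$, $F = 2\ln 128$) found by both the oracle and the
search in ≥ 9 of 10 reruns; agreement of the search with the exhaustive
oracle at `1e-9` on 100 runs over ten 3-mode mixture landscapes (modes
separated by at least ~3 sigma — closer modes are not meaningfully
distinct); monotone convergence over 50 randomized runs; exact agreement of
the morphology stages with brute force on 100 random 32×32 masks; and tumor
recovery with Dice ≥ 0.90 on 10 phantom seeds at noise sigma 5 and 8.

The opposition-learning ablation compares DOBES and BES on the phantom
histogram at a deliberately starved budget (30 iterations, single rerun).
The measured mean paired gain is small (~0.008 entropy units) against a
per-pair standard deviation of ~0.035, so the comparison uses 100 paired
seeds: the standard error of the mean difference (~0.0035) then sits well
below the effect, making the sign of the mean a meaningful check rather
than a coin flip. The two optimizers consume different RNG streams, so
pairing by seed aligns budgets, not trajectories.

`scripts/acceptance.R` re-runs all of the above from scratch at a
user-supplied seed and writes the resulting quantities as JSON; it uses the
same problem sizes as the tests.

## Limitations

* Kapur's entropy, not the optimizer, decides where thresholds go; under
  heavy class-mass imbalance or near-zero noise the optimum can be
  degenerate (grouped classes, duplicated thresholds). The package treats
  this as observable behavior and tests it, rather than papering over it.
* The morphology chain assumes one bright, compact, roughly convex target;
  ring-shaped or multi-focal targets will be mis-selected by design.
* The final region is biased outward by about the dilation radius.
* 2-D slices only; no DICOM/NIfTI readers (PNG/TIFF/JPEG via the respective
  R packages; BMP is not supported because no installed reader exists).
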