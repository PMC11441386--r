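---
title: "Generating and evaluating two-tone Mooney images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating two-tone Mooney images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mooneyr)
```

## The problem

A Mooney image is a photograph reduced to two tones: every pixel fully black
or fully white. Observers can often still recognize the depicted object —
but only by resolving substantial ambiguity, which is what makes these
stimuli valuable for studying the interaction of low-level image content and
high-level interpretation. The traditional construction is manual: smooth
the photograph to suppress noise, then adjust a binarization threshold by
eye. `mooneyr` automates both steps and provides the statistics needed to
characterize what the automation produces.

The pipeline is deliberately restricted to **global** thresholding — a
single cutoff applied to the whole image. Global thresholds preserve the
ordering of pixel intensities: if a pixel is white at threshold $t_2$ it is
white at every $t_1 < t_2$. Two consequences are load-bearing for the
package's guarantees. First, the candidate space is tiny: an 8-bit image
admits exactly 256 distinct thresholds, so the spatial selectors can search
it exhaustively rather than heuristically. Second, two Mooney variants of
the same image can never be full polarity reverses of each other, which
bounds the dissimilarity ratio of any two variants strictly below 1 (for
thresholds inside the image's intensity range). Local, region-adaptive
thresholding breaks both properties and is out of scope.

## The pipeline and its assumptions

1. **Grayscale.** A weighted channel sum with the CIE1931 luminance
   coefficients for sRGB primaries, $(0.2126, 0.7152, 0.0722)$, applied
   directly to the stored 8-bit values. Whether stored values should first
   be gamma-decoded to linear intensities is genuinely ambiguous — common
   scientific-imaging toolchains apply the weights to stored values, but
   "linear intensity" can also be read as linearized sRGB. Both paths are
   implemented (`gamma_decode` in `to_grayscale()`); the direct path is the
   default and is what every downstream default assumes.
2. **Smoothing.** Convolution with a normalized separable Gaussian,
   standard deviation $\sigma$ pixels, truncated at $4\sigma$ (kernel radius
   $\lfloor 4\sigma + 0.5 \rfloor$). Because the kernel is a convex
   combination, smoothing can never leave the input intensity range and
   preserves constant images exactly — both are asserted as tests. The
   boundary is extended by half-sample mirror reflection by default;
   replicate and circular modes are available. Reflection was chosen because
   zero-padding would darken borders and thereby bias the mean threshold
   downward on every image.
3. **Quantization.** Round half away from zero, clip to $[0, 255]$. This
   rule is exactly reproducible across platforms, which matters because all
   four selectors operate on the quantized image: a one-bit difference in
   quantization could move a selected threshold.
4. **Threshold selection and binarization.** A pixel becomes white iff its
   intensity **strictly exceeds** the threshold ("exceeding" read
   literally; pixels equal to the threshold are black). With this
   convention $t = 255$ gives an all-black image, so the inclusive
   candidate range $0\ldots255$ contains both degenerate binarizations.

The template edge map used by the edge-similarity selector is computed from
the *quantized, smoothed* image — the same object the candidate thresholds
are applied to — so template and candidates live on the same intensity grid.

## The four selectors

**Mean.** The arithmetic mean of all pixel intensities, kept real-valued:
the comparison during binarization is against integer pixel values, so
rounding the threshold would only discard information. A baseline that any
lab can reproduce without further choices.

**Otsu.** The integer $t$ maximizing the between-class variance
$\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2$ of the black
($\le t$) and white ($> t$) classes, computed from the 256-bin histogram by
cumulative moments. The implementation is checked, fixture by fixture,
against an exhaustive search that recomputes both class means directly for
each of the 256 candidates, and against an independent library
implementation (to within one histogram level, since binning grids differ).

**Max edge.** For each candidate $t$: binarize, run the Canny detector on
the result, count edge pixels; return the count-maximizing $t$. Maximizing
the *number* of edge pixels (rather than an edge-information functional) is
the simplest member of this family and tends to select thresholds that
expose as much image structure as possible — including structure absent
from the template.

**Edge similarity.** Compute the template's Canny edge map once; for each
candidate $t$, measure the directed Hausdorff distance from template edge
pixels to the candidate's edge pixels; return the minimizing $t$. The
directed form — template → candidate, not the symmetric maximum — penalizes
template edges that the Mooney image fails to reproduce, while not
penalizing extra candidate edges; a `symmetric` flag provides the symmetric
variant. A template with an empty edge map is an error: the objective would
be identically zero and the argmin meaningless.

### Numerical and degenerate-input choices

* **Tie-breaking.** All argmax/argmin searches and Otsu break ties toward
  the smallest threshold. The choice is arbitrary but fixed, and documented
  because a different tie rule is observationally equivalent only on images
  without objective plateaus.
* **Search enumeration.** All 256 candidates are enumerated and the
  objective curve always has 256 entries. Candidates falling between the
  same two occupied intensity levels produce byte-identical binarizations,
  so the expensive inner evaluation (Canny, Hausdorff) is computed once per
  distinct binarization and shared; every curve entry equals what a literal
  256-iteration loop computes, which the tests verify against exactly such
  loops.
* **Empty edge sets in the Hausdorff distance.** Distance from an empty
  template is 0; distance *to* an empty candidate edge set is the image
  diagonal $\sqrt{H^2+W^2}$ — an upper bound on any realizable distance —
  so all-black/all-white candidates lose the argmin rather than crash it.
* **Canny details.** Gaussian smoothing at the detector's own
  $\sigma$ (default 1 px), Sobel gradients, non-maximum suppression, and
  hysteresis with thresholds defined as fractions (defaults 0.1 and 0.2) of
  the per-image gradient-magnitude maximum — relative thresholds make the
  detector contrast-invariant, which is what the per-candidate search
  needs. Suppression quantizes the gradient *orientation* (modulo 180°) to
  one of four neighbour axes using only $|g_x|$, $|g_y|$ and
  $\mathrm{sign}(g_x g_y)$, and keeps a pixel iff its magnitude strictly
  exceeds one fixed spatial neighbour and is at least the other. The
  asymmetric tie rule thins the two-pixel magnitude plateau of an ideal
  step edge to a single 1-pixel line. Before filtering, intensities are
  centred at 127.5: for 8-bit input, polarity reversal then negates the
  centred image exactly, negation commutes bit-exactly with the
  convolutions, and the detector's output is *identical* — not merely
  close — for polarity-reversed inputs. Hysteresis links weak to strong
  pixels through 8-connected paths.
* **Degenerate shapes.** 1×N and N×1 images are rejected by the edge
  detector (no meaningful 2-D gradient); constant images yield empty edge
  maps, a zero max-edge objective (tie-break returns $t=0$), and an error
  from Otsu (no second class) and from edge similarity (empty template).

## Evaluation statistics

The dissimilarity ratio between two equal-sized binary images is the
fraction of disagreeing pixels — a normalized Hamming distance, hence
symmetric, zero exactly on identical images, and triangle-inequality
compliant; all three axioms are property-tested. Per-image spread of the
four selectors is summarized by the sample standard deviation (denominator
$n-1$, the default of mainstream statistics stacks; a population option
exists). Distribution summaries use linearly interpolated quartiles
(`quantile` type 7) and Tukey whiskers (most extreme points within
1.5 IQR); both conventions are stated because neither is universal. The
pairwise dissimilarity matrix averages ratios over images with equal
weight. Difficulty stratification maps identification accuracy $p$ to
easy ($p > 0.75$), medium ($0.25 < p \le 0.75$) or difficult
($p \le 0.25$) — boundaries sit *in* the lower class, so the three groups
partition $[0,1]$ exactly.

## Foil selection

For a forced-choice identification task, foil answers should be confusable
with the target in shape, not in meaning. Given a concept embedding (rows =
concepts, columns = named dimensions), `project_shape()` restricts it to a
named subspace — by default the 13 shape-related dimensions of the
49-dimensional THINGS similarity embedding (`shape_dimensions()`) — and
`select_foils()` returns the $k$ nearest other concepts by Euclidean
distance in that subspace. Dimensions are matched case-insensitively
(published column labels vary in capitalization), raw values are used
without standardization (the embedding's dimensions are already on a common
scale by construction), and distance ties break alphabetically so results
do not depend on row order. The selection is verified against an
exhaustive-distance search on randomized toy embeddings; the package does
not bundle or download the THINGS embedding itself.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` generates the test battery: intensity ramps (full 0–255
coverage, known mean), bimodal scenes (a disk-shaped object blob at
$N(200, 10^2)$ on a $N(40, 10^2)$ background — cleanly separable histogram
classes, so mean and Otsu are well defined and distinct), nested rectangles
at intensities 60/120/180 (known edge geometry with two nested contours),
disks, uniform noise (high-frequency content that smoothing must suppress),
and polarity pairs (a binary image and its exact complement, whose
dissimilarity ratio is 1 by construction). All randomness uses the
Mersenne-Twister generator with Inversion normals, explicitly named and
seeded and restored afterwards, so fixtures are byte-identical across runs
and platforms.

These fixtures exercise every code path and every documented invariant, but
they are not photographs: they lack textured clutter, lighting gradients,
and the long-tailed intensity histograms of natural scenes. Passing tests
therefore demonstrate algorithmic correctness (selectors equal their
exhaustive oracles, metrics satisfy their axioms, the pipeline is
deterministic), not that any particular technique produces *interpretable*
Mooney images of natural photographs — interpretability is an empirical,
observer-level question outside the package's scope.

## Parameters that matter

| parameter | default | unit | notes |
|---|---|---|---|
| smoothing σ | 2 | px | the smallest value that removes pixel noise while keeping the characteristic patchy look; 2–6 is the useful range, beyond 6 contours degrade. `run_batch(sigmas = c(2, 4, 6))` spans it, giving 12 variants per template |
| truncation | 4 | ×σ | kernel support cutoff; fixed across the package |
| Canny σ | 1 | px | detector scale for both spatial selectors |
| Canny low / high | 0.1 / 0.2 | fraction of max gradient | hysteresis thresholds; common detector defaults, configurable (`--canny-low`, `--canny-high`) |
| grayscale weights | 0.2126, 0.7152, 0.0722 | — | CIE1931 luminance; configurable |
| foils k | 3 | concepts | three foils + correct answer = four-alternative task |

## Problem sizes and limitations

The test suite and the acceptance script run the exhaustive-oracle
comparisons on 50+ seeded fixtures between 24×24 and 64×64 pixels — sizes
at which a literal 256-iteration Canny/Hausdorff reference loop is cheap to
run alongside the implementation. The pipeline itself is resolution-
independent and processes 800×800 photographs; only the dual-route oracle
testing is kept small. Known limitations: no colour management or ICC
handling (channel weights are applied to stored values); no image resizing
(inputs are used at their native resolution); no local thresholding; the
Canny non-maximum suppression uses 4-axis orientation quantization rather
than sub-pixel interpolation, so edge maps from different Canny
implementations can differ at exact 22.5° orientation boundaries — within
this package all comparisons use its own detector on both sides of every
objective, so selections are internally consistent.
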