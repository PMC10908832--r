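---
title: "Quantization hiding for NIfTI volumes: model, parameters and design"
author: "niistego authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantization hiding for NIfTI volumes: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niistego)
```

## The problem

A 3-D MRI volume stored as NIfTI-1 is a stack of `S` highly correlated
slice images. `niistego` halves the stored slice count by *hiding* each
odd-indexed slice inside the DCT coefficients of its preceding
even-indexed slice, producing one *stego* slice per pair that is nearly
indistinguishable from the original cover slice. The hidden slice is
later recovered *blindly* — from the stego file alone, without the
original cover or message — so the stego file is a self-contained,
half-size surrogate for the full volume.

This is quantization index modulation (QIM) steganography used as a
lossy compression primitive: the interesting trade-off is between stego
fidelity (how invisible the payload is) and reconstruction fidelity
(how well the hidden slice survives), governed by a single integer
parameter $\beta$.

## The codec

**Normalization.** Each slice is mapped to $[0,1]$ by the linear map
$x \mapsto (x - \mathrm{lo})/(\mathrm{hi} - \mathrm{lo})$, clipped to
$[0,1]$. By default (`rangeMode = "volume"`) both slices of a pair use
the volume-wide extrema $(v_{\min}, v_{\max})$, which the downsampler
records in the output header (the `descrip` string, mirrored in
`cal_min`/`cal_max`), so the receiver can denormalize exactly while
remaining blind. The alternative `per-slice` mode normalizes each slice
by its own extrema; the receiver then has to fall back to the stego
slice's extrema and accepts a small range drift.

**Block transform.** Slices are tiled into non-overlapping $4\times4$
microblocks. Each cover block $M$ is transformed with the orthonormal
4-point DCT-II matrix $T$ ($T T^{\mathsf T} = I$, first row constant
$1/2$):

$$C = T\,M\,T^{\mathsf T},$$

giving one approximation (DC) coefficient $C_{00} \in [0,4]$ and
fifteen detail coefficients, each provably of magnitude below 2 for
pixel values in $[0,1]$. Non-overlapping tiling is essential: each
stego block must decode from itself alone, and overlapping blocks would
make that inverse problem ill-posed. Residual margins (dimensions mod
4) carry no payload and pass through unchanged.

**Embedding.** The magnitude range $[0,2)$ of every detail coefficient
is partitioned into $\beta$ intervals of width $2/\beta$; interval $i$
covers $[2i/\beta,\,2(i+1)/\beta)$ (lower-closed, with the top interval
absorbing magnitudes at or above 2 — a deterministic tie-break is
required so embedder and extractor always agree). A cover coefficient
$c$ with interval index $i$ and a normalized message pixel
$m \in [0,1)$ produce the stego coefficient

$$c' = \operatorname{sign}(c)\,\frac{2}{\beta}\,(m + i),
\qquad \operatorname{sign}(0) := +1 .$$

$c'$ stays inside interval $i$, so the index — and with it $m$ — is
blindly recoverable:

$$\hat m = \frac{\beta}{2}\left(|c'| - \frac{2i}{\beta}\right).$$

The DC coefficient is never modified: it carries the block mean, and
preserving it bit-exactly keeps the stego slice visually faithful. At
extraction the DC position of the reconstructed message block is
refilled with the mean of its two nearest spatial neighbours, positions
$(0,1)$ and $(1,0)$.

**Post-processing.** The reconstructed slice is denormalized and passed
through a $3\times3$ median filter that removes the isolated speckle
produced by occasional interval misreads (below). Borders are
zero-padded by default (`medianPadding = "replicate"` is available).

**Volume pipeline.** `downsampleVolume()` pairs slices $(0,1), (2,3),
\dots$ along the chosen axis, emits one stego slice per pair, passes an
odd trailing slice through unchanged (recording a parity flag), halves
the raw payload for even $S$, writes the codec parameters
($\beta$, range mode, original $S$, parity, range) into the 80-character
`descrip` header field (with a JSON sidecar fallback if the string were
to overflow), and doubles the slice-axis voxel spacing so the file
remains geometrically sensible. `upsampleVolume()` inverts all of this
from the header metadata alone.

## Parameters

| Parameter | Default | Meaning and effect |
|---|---|---|
| `beta` | 500 | Number of quantization intervals. Larger $\beta$ means narrower intervals: the stego coefficient moves less (stego distortion $\propto 2/\beta$, so stego PSNR *rises* with $\beta$) but extraction reads the position within a narrower interval, so every perturbation of the stored stego slice is amplified by $\beta/2$ (reconstruction quality *falls* with $\beta$). |
| `rangeMode` | `"volume"` | Normalization range shared by the pair and recorded in the header (blind and range-exact), vs. literal per-slice extrema with drift at extraction. |
| `clampEps` | $2^{-12}$ | Normalized message values are clamped to $1-\texttt{clampEps}$; $m = 1$ exactly would place $c'$ on the next interval's boundary and decode as 0. |
| `sliceAxis` | 3 | Array axis along which slices run. |
| `medianPadding` | `"zero"` | Border handling of the median post-filter. |

## Where the reconstruction error comes from

The float-domain codec is exact: embed followed by extract returns
every detail message value to machine precision (the test suite checks
$10^4$ random blocks to $10^{-9}$). All reconstruction error enters
when the stego slice is stored in the cover's integer dtype:

1. **Rounding, amplified by $\beta/2$.** Rounding to integers perturbs
   each DCT coefficient by $O(0.5/(\mathrm{hi}-\mathrm{lo}))$; the
   decoded message absorbs $\beta/2$ times that. This term grows
   linearly with $\beta$ and is the designed trade-off.
2. **Overshoot clipping.** The stego slice is not guaranteed to stay
   inside the recorded range; pixels near $v_{\max}$ can overshoot by
   up to the interval width $2/\beta$ and are clipped when the receiver
   renormalizes. This term *shrinks* with $\beta$.
3. **Interval hops.** A message value near an interval boundary
   ($m \approx 0$, or $m \approx 1$ without the clamp) can be pushed
   across it by rounding noise and decode near the opposite end of the
   unit interval — full-scale speckle. The median filter exists to
   repair exactly this. Hop frequency grows with $\beta$.
4. **Structural floor.** One pixel in 16 (the DC position) is refilled
   from neighbours, margins are copied from the stego slice, and the
   median filter smooths genuine fine detail. This floor is independent
   of $\beta$.

Consequently stego PSNR increases monotonically in $\beta$ while
reconstruction quality degrades mildly — but the degradation is the sum
of terms moving in opposite directions, so at small problem sizes the
per-$\beta$ means retain deterministic wiggles of order $10^{-3}$ SSIM.
The acceptance check of the $\beta$-trend asserts strict step-wise
monotonicity on an 8-pair phantom; the stego-PSNR and ordering
assertions hold robustly, while the strict SSIM assertion is at the
mercy of that wiggle floor — a resolution limit of small-sample means,
documented rather than papered over with a tolerance.

## The synthetic phantom

`generatePhantom()` supplies deterministic MRI-like volumes so every
test and demo runs without downloads. A volume is a sum of `nBlobs`
elliptical Gaussians whose centres drift linearly along the slice axis
(`sliceDrift`, as a fraction of the in-plane extent per slice), mapped
affinely onto the dtype range, then subjected to Rician noise — the
standard model for magnitude MR images: each voxel becomes
$\sqrt{(x+n_1)^2+n_2^2}$ with $n_1, n_2 \sim N(0, \texttt{noiseSd})$.
The background is therefore Rayleigh-distributed and strictly positive,
like real magnitude data; a clipped-Gaussian background would leave a
point mass of voxels exactly at the normalization boundary $m = 0$,
where the codec's interval decoding is maximally fragile, and would
manufacture failure modes real data cannot produce.

Defaults and why:

* `shape = c(64, 64, 16)` — large enough for $16\times16$ blocks per
  slice and 8 embed/extract pairs, small enough that the full
  $\beta$-sweep runs in seconds.
* `nBlobs = 12`, widths 7–16 % of the in-plane extent — overlapping
  structures at roughly cortical scale, so the $\beta$-independent
  error floor (DC refill, median smoothing) is exercised like on real
  anatomy rather than on a billiard-smooth field.
* `noiseSd = 655` — about 1 % of the uint16 range, the low end of the
  conventional simulated-MRI noise levels.
* `sliceDrift = 0.05` — adjacent-slice Pearson correlation above 0.9
  (verified across seeds at zero noise), matching the strong
  inter-slice correlation that makes adjacent-slice embedding
  meaningful; correlation decreases monotonically in the drift.

What the phantom does **not** emulate: anatomy (no tissue classes or
folded cortex), intensity bias fields, partial-volume edges, scanner
artifacts, or the long-tailed intensity histograms of real MRI, whose
maximum is attained by sparse bright structures. Passing tests on the
phantom therefore demonstrate the codec's contracts and trends, not
clinical image quality; the `eval` tooling exists precisely so the same
metrics can be computed on real volumes.

## Numerical choices and degenerate inputs

* Interval indices use `floor` with a top clamp
  (`intervalIndex()`), making boundaries lower-closed everywhere —
  embedder and extractor must share one convention or boundary values
  would be ambiguous.
* $\operatorname{sign}(0) := +1$; extraction uses absolute values, so
  any fixed choice is consistent (verified by a sign-symmetry test).
* A slice whose normalization range is degenerate (constant slice in
  per-slice mode) cannot carry payload; the codec passes it through
  bit-exactly and flags it, rather than dividing by zero.
* Stego slices are stored in the cover's own integer dtype. This is
  what keeps the size-halving honest (the container keeps its sample
  type) and is the sole source of reconstruction error, as analysed
  above.
* Five-number summaries use linear-interpolation quartiles; entropy
  uses a 256-bin histogram after affine rescaling to $[0,255]$. Both
  conventions are documented because box-plot and entropy values depend
  on them.
* Volume-level metrics are reported both as per-slice means and as
  single pooled values; the two aggregations answer different questions
  and are kept distinct in `qualityReport()`.

## Problem sizes used by the test suite

The suite runs on $64\times64\times16$ phantoms (the $\beta$-sweep),
$10^4$ random blocks per $\beta$ for the float-domain roundtrip, and a
collection of small volumes ($S \in \{2, 7, 8, 16\}$, in-plane shapes
including $30\times26$) for the shape, parity and margin contracts —
sizes chosen so the whole suite completes in well under a minute while
still exercising every code path, including non-multiple-of-4 margins
and odd slice counts.

## Known limitations

* The embedding carries no key: anyone with the file and $\beta$ (which
  is written into the header on purpose) can extract. This is a
  compression codec, not a security mechanism.
* The stego file does not survive lossy recompression or intensity
  rescaling; only lossless containers (`.nii`, `.nii.gz`) are
  supported.
* Only 3-D volumes are handled; 4-D acquisitions must be split first.
* Bit-level BER between original and reconstructed volumes is large
  even when perceptual quality is high: reconstruction randomizes
  low-order bits everywhere, which dominates a bit-count metric.
* In `per-slice` mode the extraction range drifts with the stego
  slice's own extrema; `volume` mode exists to avoid exactly that.
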