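---
title: "Block-based multi-focus fusion for fluorescence z-stacks: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based multi-focus fusion for fluorescence z-stacks: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focusfuse)
```

## The problem and the model

A widefield fluorescence microscope images one focal plane per exposure, and
its depth of field is far smaller than the relief of a thick specimen. A
z-stack — N frames of the same visible area at increasing object distance —
contains every structure in focus *somewhere*, and fusing it means deciding,
per region, which frame that is. Two properties of fluorescence optics shape
the method:

* **luminosity tracks focus**: a fluorescent structure emits into the
  detection path most efficiently at its own focal plane, so its in-focus
  frame is also its brightest;
* **out-of-focus light contaminates**: with no confocal pinhole, a bright
  structure that is *out* of focus spreads light over its neighbourhood.
  Per-pixel rules (maximum projection, weighted averages) are defenceless
  against this: a dim region's own modest in-focus signal loses to the
  defocused halo of a bright neighbour.

The method therefore works block-wise. The image is tiled into m×n blocks
$B_{j,k}$, and the patch $p_{i,j,k}$ (frame $i$'s pixels inside $B_{j,k}$)
is scored with

$$s_{i,j,k} = m_{i,j,k} \times \mathrm{var}_{i,j,k}, \qquad
\mathrm{var}_{i,j,k} = \frac{1}{mn}\sum_{v_{r,s} \in p_{i,j,k}}
  (v_{r,s} - \mu_{i,j,k})^2,$$

the product of the patch maximum (the luminosity cue) and the *population*
variance of patch intensity (the texture/clarity cue). The block's depth is
$\mathrm{index}_{j,k} = \arg\max_i s_{i,j,k}$, ties resolved to the smallest
frame index for determinism. Either factor alone fails in a characteristic
way — variance alone locks onto high-contrast defocused halos, the maximum
alone ignores texture — while their product needs a candidate plane to be
bright *and* resolved. Four classical measures (variance, normalized
variance, a 4-neighbour Laplacian, local maximum) are implemented alongside
for comparison, and `max_projection()` provides the confocal-style per-pixel
baseline.

Frame indices are 1-based throughout (frame 1 = shallowest plane), physical
depth is $z_0 + (\mathrm{index}-1)\,\Delta z$, and the void sentinel is `NA`
in memory and 0 in exported rasters (1-based indices leave 0 free in files).

## Cleaning the block map

**Confidence (Eq.-level rule).** $C_{j,k}=1$ iff the selected patch's
maximum *strictly* exceeds `threshold0`. A block that is dim even in its
chosen frame carries no reliable focus evidence — whatever light it shows
may be someone else's defocused halo.

**Voting adjustment.** Within each block's $(2\cdot\mathrm{kernel}+1)^2$
window (clipped at the grid border, no padding), confident blocks vote:
`vote_num` of them, of which `pos_vote` differ from the centre's index by
more than `threshold1`. If `pos_vote > ratio * vote_num` **and**
`vote_num > threshold2`, the centre is replaced. Design choices the
algorithmic statement leaves open, fixed here:

* the replacement value is the rounded mean of the *disagreeing* confident
  voters — the evidence that outvoted the centre (the centre itself can
  never be in that set, so it is implicitly excluded);
* rounding is half-up (`floor(x + 0.5)`), so results cannot depend on the
  parity tie-break of banker's rounding;
* the update is **synchronous**: every window reads the pre-pass map and a
  single pass is made, so the result is independent of block scan order
  (the unit tests include a fixture where a sequential in-place pass would
  give a different answer).

**Unconfident filling.** Every $C=0$ block then takes the rounded mean index
of the confident blocks in the same window; with no confident neighbour it
becomes void. "Near" is deliberately the same window as the voting step —
the only neighbourhood the procedure defines.

## Per-pixel refinement and assembly

Blocks quantize depth, so a depth step crossing the middle of a block would
otherwise produce blocking artifacts. After broadcasting block indices to
pixels, **information filling** visits every 4-adjacent block pair (raster
order: horizontal pairs, then vertical) whose block-level indices differ by
more than `threshold3` and of which at least one member is confident. A
pixel in either block switches to the other block's *block-level* index $x$
iff $v_{d} < \texttt{threshold4}$ and $v_{d} < v_{x}$, where $d$ is the
pixel's current index. Updates are immediate (a pixel may be revised by a
later pair), mirroring the sequential statement of the procedure; $x$ is
the neighbouring block's index, not the neighbouring pixel's. Void blocks
never participate in pairs.

The fused image copies each pixel from its assigned frame (void pixels
render as 0, the same convention as masked regions in the per-object mode),
so before smoothing every non-void pixel is a bit-copy of exactly one
source pixel — a property the tests assert and the acceptance script
measures. Gaussian smoothing (sigma default 1 px, kernel truncated at
3 sigma, symmetric-reflection borders) is applied only inside a band of
±2 px around block boundaries where the index changes, in both the fused
image and the *physical depth* raster — never the integer index map, which
would invent source frames. Smoothing is the last step, after depth
conversion, so both exported rasters see the same treatment.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `block_h`, `block_w` | px | 15 | block size; small enough that depth is near-constant within a block, large enough to average out contamination |
| `threshold0` | intensity | 60 | confidence cut on the selected patch maximum |
| `kernel` | blocks | 2 | voting/filling window radius (5×5 window) |
| `threshold1` | frame indices | 40 | disagreement distance for a vote |
| `threshold2` | count | 4 | minimum confident voters |
| `ratio` | — | 0.5 | disagreeing fraction that triggers replacement |
| `threshold3` | frame indices | 10 | pair gap that opens information filling |
| `threshold4` | intensity | 80 | brightness guard: such pixels are never reassigned |
| `smoothing_sigma` | px | 1 | seam smoothing width; 0 disables |

Intensity thresholds are in raw units and scale with bit depth: the defaults
are for 8-bit stacks (the native range is kept on read precisely so these
numbers stay meaningful; nothing is normalized to [0,1]). For 16-bit data
multiply `threshold0`/`threshold4` by 257 as a starting point.

## The synthetic generator

No public reference stacks exist for this instrument class, so the package
generates its own study material with known ground truth. A scene is a
height map $Z(p)$ in frame-index units plus an emission texture $E(p)$;
frame $i$ renders as

$$\mathrm{frame}_i(p) = \mathrm{GaussBlur}(E, \sigma(p,i))(p)\cdot
  \mathrm{gain}(p,i) + \varepsilon, \qquad
  \sigma(p,i) = \texttt{blur\_rate}\,|i - Z(p)|,\quad
  \mathrm{gain}(p,i) = \frac{1}{1 + \texttt{atten\_rate}\,|i - Z(p)|},$$

clipped to the working range and rounded to integers; $\varepsilon$ is
additive Gaussian read noise (Poisson shot noise is deliberately not
modelled — additive noise keeps the variance accounting in tests exact).
The hyperbolic (not Gaussian) brightness fall-off keeps dim structures
nonzero at every plane, so confidence thresholds can actually be exercised.
Blur sigmas are quantized to 0.5 px and the blurred layers cached, making
rendering deterministic and cheap; defaults are `blur_rate = 1` px/step,
`atten_rate = 0.05`/step and `noise_sd = 2` — a defocus growth and ~5% per
step brightness loss typical of a high-NA widefield objective stepped at
its depth of field.

Scene kinds: `two_plane` (block-aligned depth step; set `align` to a
non-multiple of the block size to put the step *inside* a block and
exercise information filling), `staircase`, `hemisphere` (smooth dome
spanning the full index range), and `blob_and_dim_texture`. The last is the
contamination scenario: a saturated blob at the deep plane beside dim
texture (30–80 of 255) at the shallow plane, with `blur_rate = 2.5` and no
noise so the defocused blob floods the dim region. On it, the per-pixel
argmax baseline is wrong on over half the dim region while every confident
dim block keeps its true depth under the proposed measure — the computable
analogue of the qualitative comparison the block measure was designed to
win.

What the generator does **not** emulate: Poisson statistics, depth-dependent
PSF asymmetry (spherical aberration), scattering, bleaching between planes,
and lateral drift. Passing tests on these scenes therefore demonstrate the
pipeline's logic — measure behaviour, voting, filling, provenance — not
instrument-calibrated accuracy on real tissue.

Renderings at the default physics violate "a pixel is brightest at its own
plane" on textured scenes — dim pixels are outshone by defocused bright
neighbours — and that is intended: it *is* the contamination premise. The
attenuation law alone (with `blur_rate = 0`), or a constant texture,
recovers the strict per-pixel property, and the tests check exactly those
two regimes.

## Numerical and interface choices

* **Edge blocks** keep their actual size (no padding); the $1/(mn)$ in the
  variance is the actual pixel count there, since zero-padding would bias
  the variance.
* **Laplacian baseline**: 4-neighbour kernel
  $[[0,1,0],[1,-4,1],[0,1,0]]$, mean absolute response, replicated borders;
  the upstream citation names no formula, so this is a documented,
  swappable approximation of the *comparison*, not of the proposed measure.
* **Normalized variance** of an all-dark patch ($\mu = 0$) is defined as 0:
  darkness carries no focus evidence.
* **Per-object mode** (optional): objects are detected on the maximum
  projection — the brightest evidence across depth — via DBSCAN (own
  grid-hashed implementation; `fof` preset = `min_samples 1`, since
  friends-of-friends is DBSCAN's linking special case) or 4-connected
  components. Block size per object uses an explicit ladder rule: largest
  ladder entry ≤ `max(min_block, min(bbox)/divisor)`. The source procedure
  names no scale→size mapping, so this rule is the module's main documented
  gap. Unassigned pixels join their nearest labelled pixel by exact
  Euclidean distance (two-pass exact distance transform), ties to the
  smaller label; masked-out pixels are 0 in every class's frames, and each
  output pixel is written by exactly one class. A single all-image class
  reproduces the plain pipeline bit-exactly before smoothing.
* **Depth raster on disk** is 32-bit float TIFF storing depth normalized by
  a scale factor recorded in `run.json`; `read_depth_map()` restores
  micrometers (exact to single precision). Index maps are 16-bit with 0 as
  void; integer rasters round-trip bit-exactly.
* **Determinism**: identical configuration and seed give bit-identical
  outputs; all randomness flows through the scene seed.

## Problem sizes used in the checks

The bundled checks run on sizes chosen to exercise every code path at
interactive speed: oracle comparisons on ~20 random stacks up to
128×128×8 with block sizes 5–40; the noisy recovery benchmark on a
256×256, 20-plane hemisphere (RMSE over confident blocks whose true depth
range is ≤ 1 frame, i.e. away from the rim discontinuity, comes out an
order of magnitude below one focal step); contamination on a 120×120,
12-plane blob scene. Real pollen-scale stacks (≈1920×1200×81) run through
the same code path; only runtime grows.

## Known limitations

* A single pass of voting adjustment, as specified — no iteration to a
  fixed point (the clean-scene fixed-point property is tested instead).
* Block boundaries of the *initial* grid define the smoothing band; seams
  introduced inside blocks by information filling are intentionally left
  sharp (they are object boundaries, not artifacts).
* Depth at object edges inherits the weaker voting support there; the
  per-object mode with smaller blocks is the intended mitigation.
* No registration: frames are assumed co-registered, and proprietary
  vendor formats are out of scope (TIFF/PNG only).
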