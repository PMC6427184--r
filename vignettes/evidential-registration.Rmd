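---
title: "Evidential fusion of candidate transformations for image registration"
author: "evireg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential fusion of candidate transformations for image registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evireg)
```

## The problem

Registering a sensed image $S$ to a reference image $R$ means estimating
the spatial transformation $T$ that aligns them.  Practitioners face a
choice with no single right answer: which keypoint detector (sparse
route), or which similarity measure (dense route), should drive the
estimation?  Different choices produce different transformations, each
with its own failure modes.  `evireg` treats this *selection uncertainty*
with the theory of belief functions: every candidate transformation
$T_1, \dots, T_Q$ becomes a hypothesis in a frame of discernment
$\Theta$, evidence for each candidate is collected from three independent
views of the image content, the evidence is combined with Dempster's rule
or with PCR6 (proportional conflict redistribution), and the fused masses
yield a single combined transformation.

## Geometry and conventions

All transformations are projective, acting on **row** homogeneous
coordinates: $[g\; h\; s] = [v\; w\; 1]\,T$ with the 3x3 matrix $T$
normalized to $t_{33} = 1$.  A point $(v, w)$ is (column, row), 0-based,
with pixel centers on the integer lattice; this convention was fixed once
and is enforced at every boundary (detector adapters, warping,
serialization — transform files carry a `"convention": "row-vector"` tag
and loading refuses files without it).  Rigid motions are parameterized
by $(\theta, t_v, t_h)$: an anticlockwise rotation in degrees applied
before a translation in pixels, i.e. the unit-scale similarity matrix
with rows $[\cos\theta, \sin\theta, 0]$, $[-\sin\theta, \cos\theta, 0]$,
$[t_v, t_h, 1]$.

Warping is inverse mapping: each output pixel is mapped through $T$ into
the source frame and resampled (bilinear by default; nearest kept for
exactness tests).  Out-of-frame sources fill with 0 and are flagged in a
validity mask.  The projective model has 8 degrees of freedom, so four
correspondences with no three collinear determine it exactly; with more
correspondences the package solves the normalized DLT (Hartley
normalization, SVD) and refines the summed **squared** reprojection
distance with Levenberg–Marquardt.  The literal sum of (non-squared)
Euclidean distances is available as a cost option; the squared form is
the numerically standard reading of least-squares fitting and is the
default.

## Candidate generation

**Sparse route.**  Keypoints with descriptors are detected behind a
pluggable registry.  Three classical families are built in — Harris
corners, Shi–Tomasi (minimum-eigenvalue) corners, and
difference-of-Gaussians blobs — each normalized to the package's
coordinate convention and sharing an L2-normalized 8x8 intensity-patch
descriptor sampled from a smoothed image ($\sigma = 2$).  Descriptors are
*upright* by default: dominant-orientation estimation is noise-sensitive,
and a wrongly estimated frame costs far more matches than the modest
view rotations this tool targets; rotation invariance can be switched on
per detector (`orient = TRUE`).  Matching uses the Lowe ratio test
(default 0.8) with greedy one-to-one resolution; mismatches are removed
by MSAC (default; RANSAC available) over exact 4-point fits with a 2 px
reprojection threshold and 2000 seeded iterations, followed by an LS
refit on the consensus inliers.  A second, geometry-guided round then
re-matches keypoints within a 5 px gate of the positions predicted by
the first fit and refits with a 3 px threshold (matching the keypoint
localization noise); the round with the higher verification score wins.
Verification scores a fit by the gray-channel NCC over the valid warp
overlap, requires at least half the frame to stay in overlap, and
rejects transforms whose local area scale leaves $[1/4, 4]$ anywhere on
the frame — degenerate projective fits can otherwise score well on a
shrunken overlap.  A candidate that fails verification is dropped from
the frame of discernment with a warning; fusion needs at least two
survivors.

**Dense route.**  Following the observation that a full projective dense
search is intractable, the dense route searches the rigid 3-parameter
space only, maximizing MI, NCC or PSNR between $R$ and the warped $S$.
The search is deterministic: an exhaustive coarse grid (defaults
$\theta \in [-30, 30]$ deg step 1, translations $\in [-30, 30]$ px step
2) followed by Nelder–Mead refinement from the best node, fenced to the
search bounds, never accepted if it regresses below the grid value.  The
objective is restricted to the valid warp overlap with a minimum-overlap
fraction of 0.5 by default: with full-frame fill-0 evaluation, large
displacements that align fill regions with dark image areas can
out-score the true optimum (we observed exactly this failure on blob
textures), while the masked objective peaks sharply at the truth.  The
full-frame variant remains available (`masked = FALSE`).  MI inside the
dense objective uses 64 histogram bins by default — a 128x128 image
populates a 256x256 joint histogram too sparsely for a stable surface —
while the standalone `mutualInformation()` keeps the 8-bit-faithful 256
bins.

## Evidence, channels, and fusion

For each surviving candidate $T_i$, the sensed image is warped into the
reference frame and compared with $R$ on three information channels
extracted independently from both images:

* **Gray**: the intensities themselves.
* **Edge**: the Canny edge map (Gaussian $\sigma = \sqrt 2$, hysteresis
  thresholds 0.1/0.2 of the maximum gradient magnitude; all
  configurable, since the canonical operator's parameters are a free
  choice).
* **Phase**: the phase-only reconstruction — inverse FFT of the
  unit-magnitude spectrum that keeps only the phase angle, min–max
  rescaled.  This channel preserves structure layout while discarding
  contrast.

The NCC here is the Pearson form (mean-removed, variance-normalized), so
its range $[-1, 1]$ holds; a constant channel (e.g. the edge map of an
edge-free region) contributes 0 by convention rather than crashing the
chain.  As in the dense objective, the per-candidate channel NCCs are
taken over the valid warp overlap: a correct candidate then scores near
1 on the gray channel, whereas with full-frame fill-0 evaluation even
the true transformation is capped far below that by the frame mismatch
and the evidence ordering degrades.  Per channel, the values are clamped to $[0, 1]$ — a negative
correlation carries no evidence *for* a candidate — stretched by
$y = e^x - 1$ to enlarge differences, and normalized into a Bayesian
BBA.  A channel whose clamped values are all zero falls back to the
uniform BBA with a warning, keeping the three-source structure intact.

The three BBAs are combined either by Dempster's rule (applied
sequentially — it is associative) or by PCR6.  Because the printed
two-source PCR6 formula does not determine the $n$-source behavior (PCR6
is not associative), the package implements the general joint $n$-source
redistribution as the default — every fully conflicting $n$-tuple of
focal elements returns its product mass to each contributor in
proportion to that source's mass — with sequential pairwise application
available for comparison.  Both rules are property-tested against
brute-force enumeration oracles on randomized small frames.

The combined transformation inverts the mass-weighted average of the
candidates' inverse matrices:
$T_c^{-1} = \sum_i m_c(T_i)\, T_i^{-1}$.  This average is gauge
sensitive for genuinely projective candidates; the package fixes the
$t_{33} = 1$ gauge before averaging (its canonical normalization
everywhere) and records the choice here because no other gauge is
singled out by the construction.  The pignistic transform is implemented
for completeness of the belief-function layer, but no decision step in
the registration chain uses it — the combined transformation is formed
directly from the fused masses, deliberately relaxing the classical
assumption that the final estimate must be an element of the frame.

## Evaluation

Quality is scored against a known ground truth by warping the
*reference* image with the composite $T_{\mathrm{true}} T_c^{-1}$ and
computing the average absolute intensity difference (AAID) to the
original — exactly zero when the estimate equals the truth, and immune
to the information loss that makes a direct $R$ vs registered-$S$
comparison misleading.  AAID is reported on the $[0,1]$ intensity scale
by default with an 8-bit display scale option, both globally and over an
even 5x5 spatial partition (remainder pixels join the trailing parts);
the global value always equals the pixel-count-weighted mean of the
parts, which the report object's validity enforces.  A masked variant
restricted to the warp validity mask exists but is off by default: the
literal definition sums over all pixels.

## Synthetic fixtures and the packaged suite

No public dataset accompanies the method, so a deterministic generator
builds textured reference images (Gaussian-blob fields, jittered
checkerboards, blob fields under an illumination ramp, and a two-scale
blob mixture mimicking stained-tissue texture) and derives sensed images
by warping with a known transformation and adding zero-mean Gaussian
pixel noise on the $[0,1]$ scale (variance 0.01 in the noisy designs,
i.e. a standard deviation of about 26 gray levels on 8-bit data), clipped
to $[0,1]$.  The checkerboard gets per-cell intensity jitter so that its
translation periodicity cannot alias the registration.

The packaged suite holds 20 scenarios over four textures at 128x128: the
rigid design $\theta = 10°$, $(t_v, t_h) = (-10, 5)$ clean and noisy,
the mirrored design $\theta = -10°$ noisy, and one mild random
projective scenario per texture (rotation within ±5°, translation within
±8 px, perspective entries within ±5e-4) clean and noisy.  Rigid
scenarios exercise the dense mode, projective ones the sparse mode.  The
suite sizes and the test-time search bounds (±15 to ±20, matching the
simulated motion) are the package's chosen experiment scale; every
scenario replays bit-identically from its JSON record, and all
generator randomness is seeded and isolated from the caller's RNG.

What the fixtures do *not* emulate: real sensor noise correlation,
illumination fields, occlusion, resolution differences between the two
views, and genuinely strong perspective.  Passing the packaged
experiments therefore demonstrates the correctness and internal
consistency of the machinery — not performance on any particular real
imaging domain.

## Numerical choices and known limitations

* Mass vectors must sum to 1 within 1e-9; no silent renormalization
  anywhere (a caller bug should surface, not vanish).  Dempster's rule
  refuses conflicts beyond $1 - 10^{-12}$.
* Subsets are bitmask-encoded over the frame order (at most 30
  elements), giving exact set semantics.
* MI uses base-2 logarithms; only the ordering matters downstream, so
  the base is a documented free choice.
* The dense coarse grid must bracket the true motion; the refinement is
  local.  Multi-start refinement is not implemented — the exhaustive
  grid plays that role.
* Rule insensitivity (Dempster vs PCR6 giving similar fused AAIDs) holds
  when the candidates are of comparable quality, which the verification
  gates promote; when a mediocre candidate survives alongside excellent
  ones, the two rules can differ relatively (PCR6 keeps more mass on the
  weaker candidate) even while the absolute AAID difference stays on the
  order of 0.01.
* The evidential layer assumes at least two candidate generators
  succeed; with one survivor there is nothing to fuse and the pipeline
  reports an error rather than silently degenerating.
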