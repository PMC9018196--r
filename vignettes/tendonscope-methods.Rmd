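---
title: "Methods: ground-truthed image analysis and multilevel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ground-truthed image analysis and multilevel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonscope)
```

`tendonscope` packages a linear image-analysis chain for medical raster
images of healing tendon tissue — enhancement, gradient and edge operators,
corner detection, patch matching, robust purification of correspondences,
and template localization — together with a multilevel comprehensive
evaluation model that ranks candidate anti-adhesion biomaterials. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the methods left choices open.

## Conventions

Images are numeric `H x W` matrices (or `H x W x 3` arrays) with
intensities in `[0, 1]`; 8-bit files are divided by 255 on read. All pixel
coordinates are `(row, col)`, 1-based, origin top-left — one convention
everywhere, so no stage can introduce an off-by-one against another. Every
function that uses randomness takes an integer `seed` and is bit-reproducible
given it; the caller's RNG state is never touched.

## Enhancement

Spatial-domain enhancement is an operator applied directly to the pixel
grid, `g = EH(f)`. Because the operator itself is a modelling choice rather
than a fixed formula, three dialects are provided: linear contrast stretch
(the default; maps the channel minimum to 0 and maximum to 1), per-channel
cumulative-histogram equalization (each pixel maps to its empirical CDF
value), and identity. All three preserve the intensity ordering within a
channel, which is the property downstream gradient-based stages rely on. A
constant channel has no dynamic range; stretching it is undefined, so it is
returned unchanged with a warning rather than silently rescaled.
Frequency-domain processing and a separate denoising stage are deliberately
out of scope.

## Gradients and edge operators

The forward-difference gradient is `Gx(i,j) = f(i,j+1) - f(i,j)`,
`Gy(i,j) = f(i+1,j) - f(i,j)`, with the Euclidean magnitude
`sqrt(Gx^2 + Gy^2)` and orientation `atan2(Gy, Gx)`; the cheaper `|Gx| +
|Gy|` approximation is available separately and always bounds the Euclidean
magnitude from above.

The Roberts, Sobel and Prewitt templates are applied as **correlation** (no
kernel flip): the templates are printed as directional masks, and
correlation preserves exactly that orientation. Border handling replicates
the nearest valid pixel (clamped indexing), which keeps the output the same
size as the input without inventing spurious border edges; a `valid_mask`
marks pixels whose stencil lay fully inside the image, and oracle
comparisons in the tests are made on that region. Sobel and Prewitt are
computed separably — smooth along one axis, difference along the other —
with the difference applied last, so regions of constant intensity cancel
exactly in floating point instead of leaving accumulation-order residue;
the equivalence with a naive nested-loop correlation is asserted to
`1e-12`.

## Corner response, selection, and NCC matching

The corner response at a pixel is `R = det(M) - k * trace(M)^2`, where `M`
is the Gaussian-weighted structure tensor of Sobel derivatives over a
window of standard deviation `window_sigma` (discrete radius
`ceiling(3 * sigma)`). Sobel, rather than plain differences, feeds `M`
because a windowed tensor presumes smoothed derivatives. `k` defaults to
0.04, the low end of the conventional `[0.04, 0.2]` interval, and values
outside it warn rather than error — the interval is a convention, not a
constraint of the algebra. `R` is strictly decreasing in `k` wherever
`trace(M)^2 > 0`, so smaller `k` is the more permissive choice.

Corner selection is greedy non-maximum suppression: candidates at or above
the threshold are visited in descending response order (ties resolved by
`(row, col)`) and accepted unless an accepted corner already lies within
`nms_radius` in Chebyshev distance. `find_corners()` sets the threshold as
a fraction (`threshold_rel`, default 0.02) of the maximum response. The
default is driven by how `R` scales: products of squared derivatives make
the peak response grow like the fourth power of local contrast, so a
structure at 40% of the scene's strongest contrast still produces about
`0.4^4 ≈ 0.026` of the maximum response. A 0.02 relative cut therefore
keeps genuine low-contrast corners while excluding flat regions (response
near zero) and edges (negative response).

Corner patches are compared with normalized cross-correlation over square
patches of half-width `patch_radius` (default 4; the summation support is a
choice, since only the score formula is fixed). NCC is mean-centred and
variance-normalized, hence confined to `[-1, 1]` and invariant to affine
intensity changes — exactly the invariance needed when the two images are
related by an unknown per-channel linear transform. Matching is
**mutual-best**: a pair is kept only if each endpoint is the other's best
score and the score reaches `min_ncc` (default 0.8). Mutual-best is the
simplest deterministic rule that yields a one-to-one match set; ambiguous
corners (e.g. identical patches from equally-sized rectangles in synthetic
scenes) simply drop out rather than being guessed.

## Robust purification: truncated-loss RANSAC

Matched correspondences carry colour pairs `(a, b)` modelled per channel as
`b_c = gain_c * a_c + offset_c` — a diagonal gain matrix plus offset. The
per-pair residual `d_n` pools channels as a Euclidean norm, and the
objective is the truncated sum `E = sum min(d_n^2, Thre^2)`: each pair
contributes at most `Thre^2`, so gross mismatches cannot drag the fit.

The fitting schedule is hypothesize-and-verify followed by refinement: 500
random minimal samples of 3 pairs (least-squares fit per channel, sample
redrawn if a source channel is constant), each scored by `E` over all
pairs; then the best model's inliers (`d_n^2 < Thre^2`) are refit by least
squares and the refit iterated until `|dE| < converge_eps` or `max_iter`.
This refinement provably never increases `E`: the refit minimizes the
untruncated sum over the current inliers, truncation only lowers
contributions, and excluded pairs already sit at their cap. The
`E_trajectory` is returned and asserted non-increasing in the tests.

Defaults: `Thre = 0.05` intensity units (5% of the dynamic range — above
the noise levels the generator emulates, well below typical mismatch
residuals), `converge_eps = 1e-8`, 500 hypotheses, sample size 3. A fit
whose inlier fraction falls below `min_inlier_frac` (default 0.25) is
flagged `low_confidence`; with fully contaminated data `E` saturates near
`n * Thre^2` and the flag fires. Grayscale data run through the same
machinery with one channel. Geometric (coordinate-warp) RANSAC is a
non-goal: the model here is photometric, over channel values only.

## Template localization by SSD

`ssd_scan()` scores every full-overlap placement of a template by the sum
of squared differences over the template support. Partial windows would
make the sum undefined, so only valid placements are scored, and the
surface is indexed by the window's **top-left anchor** — the fixture
ground truth uses the same anchor, fixing one convention for the offset.
The expanded three-term form (window energy, cross term, template energy)
is the default computational route; the direct windowed difference is kept
as a second route, and their agreement at every offset to `1e-9` is an
acceptance property. Ties at the minimum resolve to the lexicographically
smallest `(row, col)`. Square templates are the expected case; non-square
ones are accepted with a warning.

## Multilevel fuzzy comprehensive evaluation

Pairwise judgment matrices (`a[i,j]` = importance of indicator `i` over
`j`) are reduced to weights by the geometric-mean method: row products
`M_i`, n-th roots, then normalization. Row products are accumulated in log
space so an 8-indicator matrix of large entries cannot overflow. For a
perfectly consistent matrix built from planted weights `a[i,j] = p_i/p_j`
the method recovers `p` exactly up to scale — the algebraic identity the
tests verify numerically.

Validation is strict where the arithmetic is silent: entries must be
positive, the diagonal 1, and reciprocity `a[i,j] * a[j,i] = 1` must hold
within `1e-6` (violations are rejected with a repair suggestion). A
standard consistency ratio (principal eigenvalue against tabulated random
indices, `n <= 10`) is provided as a diagnostic; it is a companion check,
with `CR = 0` by convention for `n <= 2`.

The hierarchy is two levels deep — criteria over measures — and composite
weights are the products `w_i * w_j`, which sum to 1 by distributivity.
An alternative's score is the weighted sum `E_a = sum w_i v_i` of its
per-indicator evaluation values (0–100 scale by convention; the units are
declared, not enforced). Ranking is by descending score with lexicographic
tie-break. The key structural property — a weakly dominant alternative
ranks first — holds for any normalized non-negative weight vector and is
exercised over random hierarchies in the acceptance suite, mirroring the
qualitative finding that sodium hyaluronate ranks best among the three
candidate biomaterials when given dominant indicator scores. Triangular
fuzzy-number extensions are out of scope: the arithmetic here is crisp.

## Synthetic scenes: what they emulate, and what they do not

No image corpus accompanies the methods, so the generators plant exactly
the statistical structure each stage consumes:

- `make_corner_scene()`: axis-aligned bright rectangles (side 10–18 px,
  intensity 0.55–0.95 on a 0.1 background, clearance margin 6 px) whose
  vertices are the geometric corner ground truth and whose outlines are the
  edge ground truth, plus optional additive Gaussian noise. Ground truth is
  never produced by running a detector.
- `make_correspondence_scene()`: paired colour samples under a planted
  diagonal gain/offset, a planted fraction of uniform-random outliers
  (independent per channel — maximally uninformative contamination), and
  Gaussian noise on inlier targets. Source intensities are drawn from the
  subinterval of `[0, 1]` that keeps transformed values in `[0, 1]`, so
  the planted model holds exactly without clipping; noise is left
  unclipped.
- `embed_template()`: verbatim insertion at a known anchor, giving an SSD
  ground truth with minimum exactly 0.

These fixtures capture edges, corners, photometric transforms, outliers and
noise — the mathematical structure of the pipeline's assumptions. They do
**not** imitate MR tissue texture, scanner physics, anisotropic blur or
spatially correlated noise; passing tests demonstrate the algorithms'
correctness and robustness under their stated models, not clinical
performance on real scans.

## Problem sizes and numerical choices

The test and acceptance workloads use sizes at which every property is
already sharply discriminating: 16×16 images (50 replicates) for the
edge-operator oracle at `1e-12`; 24×24 for the structure-tensor oracle at
`1e-9` (the looser bound reflects the longer Gaussian accumulation); 25
seeded 96×96 scenes of 3 rectangles for corner precision/recall at a 2 px
tolerance; 200 correspondences with 30% contamination and noise 0.005
across 10 seeds for robust recovery (parameter error below 0.02, inlier
recall at least 0.95); 1000 random residual sets for the truncation bound;
20 random 32×32/8×8 pairs for the SSD expansion identity; 100 random
hierarchies each for weight recovery and dominance ranking. Degenerate
inputs have defined behaviour throughout: empty corner sets are valid,
zero-variance patches are skipped in matching, degenerate RANSAC samples
are redrawn, constant channels survive enhancement unchanged, and ties are
always broken lexicographically so every result is reproducible.

## Known limitations

- The corner detector has no sub-pixel refinement or scale selection;
  localization is within ~2 px of a true vertex by design.
- Mutual-best NCC matching drops genuinely ambiguous corners instead of
  resolving them; repetitive structures therefore yield fewer matches.
- The colour model is diagonal (no channel mixing) and photometric only.
- The evaluation hierarchy is fixed at two levels; judgment matrices must
  be supplied, not elicited.
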