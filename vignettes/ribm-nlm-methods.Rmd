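---
title: "De-speckling by cluster-restricted, rotation-compensated non-local means"
author: "ribmnlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-speckling by cluster-restricted, rotation-compensated non-local means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribmnlm)
```

## The problem

B-mode ultrasound images are corrupted by speckle: a granular, spatially
correlated interference pattern produced by sub-resolution scatterers with
random phases. Speckle is multiplicative in character, lowers contrast, and
blurs the apparent boundaries of lesions, which harms both reading by
clinicians and downstream processing (segmentation, feature extraction,
classification). Non-local means (NLM) filtering suits this problem because
tissue echotexture is highly self-similar: each pixel can be restored as a
weighted average of pixels whose *surrounding patches* look alike, wherever
those patches sit in the image.

Plain NLM has two weaknesses this package addresses. First, comparing every
patch against every other is wasteful and slow; most candidates are
irrelevant. Second, similar anatomical texture often recurs at *different
orientations*, and a raw patch distance treats a rotated twin as dissimilar.
The pipeline implemented here answers both: a clustering pre-classification
restricts each pixel's candidate set to patches with similar rotation-
invariant descriptors, and a rotation- and mirror-compensating block matcher
aligns each candidate to the target before the patch distance is measured.

## The pipeline

For a noisy image $v$ with patch radius $r$ (patches are $(2r+1)\times(2r+1)$):

1. **Guide image.** A normalized Gaussian kernel
   $G_\sigma(x,y) \propto \exp\!\big(-(x^2+y^2)/(2\sigma^2)\big)$, radius $m$,
   is convolved with $v$ (mirror boundary) to produce a blurred guide $G_b$.
   The guide is used *only* to compute features and clusters; all restored
   intensities are read from $v$ itself, so the pre-filter never doubles as a
   smoother of the output.

2. **Patch descriptors.** For every pixel, the square patch of the guide
   yields intensity-weighted central moments
   $\mu_{pq} = \sum v(x,y)\,(x-x_c)^p (y-y_c)^q$ through order 3, from which
   Hu's seven invariants $\phi_1,\dots,\phi_7$ are evaluated. $\phi_1..\phi_6$
   are invariant to translation, rotation and intensity scale; $\phi_7$ keeps
   its magnitude but flips sign under mirroring, which is what the mirror
   test exploits. The patch's intensity centroid over the inscribed circular
   support is also stored; its *direction* is the patch's orientation
   estimate.

3. **Pre-classification.** The $N$ Hu vectors (standardized per component by
   default) are clustered by K-means (Lloyd's algorithm, seeded k-means++
   initialization, Euclidean distance) into $K$ groups, and a look-up table
   maps each cluster to its member patch centers. Each pixel's NLM candidate
   set is exactly its own cluster's member list.

4. **Rotation-invariant block matching.** For target $i$ and candidate $j$:
   the mirror flag is $\phi_7(i)\,\phi_7(j) < 0$; the frame
   $R = R_u(\hat c_i)^{-1} R_u(m(\hat c_j))$ is built from the *unit* centroid
   vectors with $R_u(u) = \begin{pmatrix}u_1 & -u_2\\ u_2 & u_1\end{pmatrix}$
   and $m$ the x-component sign flip applied in the mirrored case. The
   distance is
   $d_R(i,j) = \sum_{q}\big(v_i(q) - \mathrm{In}(v_j, m(Rq))\big)^2$
   over the circular support, with $\mathrm{In}$ bilinear interpolation —
   required because rotated coordinates fall between pixels.

5. **Restoration.** $\mathrm{NLM}_p(v)(i) = \sum_{j} w_R(i,j)\, v(j)$ with
   $w_R(i,j) = \exp\!\big(-d_R(i,j)/h^2\big) / Z_R(i)$ over the cluster
   members, $Z_R(i)$ the normalizer. The self-candidate has $d_R = 0$ and
   hence the maximal raw weight.

A conventional NLM baseline (all pixels as candidates, Gaussian-weighted
square-patch distance of width $\alpha$) is provided for comparison and as an
oracle target in the tests.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `patch_radius` | 7 | patches are 15 × 15 pixels; the inscribed circle of radius 7 is the support for rotation work (a rotated circle stays inside the square) |
| `K` | `NULL` → scaled | number of clusters; 675 for a 225 × 225 image, scaled in proportion to pixel count for other sizes, minimum 1 |
| `h` | `12 * sigma` | bandwidth of the exponential weight kernel, on the scale of the summed squared patch distance |
| `kernel_sigma` | `0.5 * sigma` | Gaussian pre-filter standard deviation (pixels) |
| `kernel_radius` | 4 | pre-filter mask is 9 × 9 |
| `eps_centroid` | 1e-6 | centroid norm (pixels) below which a patch counts as isotropic |
| `seed` | 1 | drives clustering initialization and any subsampling |

All `sigma`-linked defaults are recomputed when `sigma` changes, and the
resolved set is attached to every filtered image (attribute `config`) and to
every experiment row, so any result can be reproduced from its own metadata.

```{r, eval = FALSE}
clean <- example_phantom(128, 128, seed = 1)
noisy <- add_noise(clean, sigma = 20, seed = 2)
denoised <- despeckle_ribm_nlm(noisy, denoise_config(sigma = 20, seed = 3))
evaluate_images(clean, denoised)
```

## Design choices where the design was open

**Hu normalization.** Patches are gray-valued mass distributions, so the
moments are intensity-weighted. The invariants are computed from the
*unit-mass* patch, $\eta_{pq} = \mu_{pq}/\mu_{00}$: patch size is fixed, so
there is no spatial scale to normalize away, and dividing by the mass is
exactly what makes the descriptors invariant to intensity scaling (the
classical exponent $\mu_{00}^{1+(p+q)/2}$ targets binary silhouettes whose
mass is an area, and would leave a residual intensity dependence here).
Rotation invariance and the $\phi_7$ mirror antisymmetry are unaffected by
this choice of per-order normalization and are enforced by tests.

**Features from the guide, intensities from the noisy image.** The blurred
guide stabilizes the descriptors and the clustering against noise, but the
weighted average reads the original noisy intensities: restoring from the
guide would compound two smoothers and lose detail by construction.
The $d_R$ distances are also measured on the noisy image, matching the
weights to the intensities actually being averaged.

**Square patches for moments, circular support for rotation.** Moments and
clustering use the full square patch (more signal); the rotation-dependent
distance uses the inscribed circle, because square corners leave the patch
under rotation and would need values that do not exist.

**Degenerate centroids.** An isotropic patch (uniform, or symmetric enough
that its centroid norm falls below `eps_centroid`) has no usable orientation.
Such candidates are compared *unrotated* rather than skipped: isotropic
patches do not need rotation compensation, and discarding them would thin
out exactly the smooth regions where averaging helps most. An all-zero patch
gets the zero feature vector at the pipeline layer and participates
normally; the low-level `central_moments()`/`hu_invariants()` functions
instead refuse zero-mass input loudly, so silent zeros cannot leak into
user-level feature computations.

**K-means details.** Assignment ties break to the lowest cluster index; a
cluster that empties is re-seeded at the feature farthest from its current
center (both deterministic). The within-cluster sum of squares is recorded
after every assignment and is non-increasing — the suite asserts this on
every fit. With `K = 1` and rotation disabled the whole pipeline provably
reduces to unrestricted circular-support NLM, and the suite checks that
reduction elementwise against a brute-force implementation. When many
patches are bit-identical (constant images), fewer than `K` clusters may end
up populated; unused clusters are legal and never referenced.

**Borders.** Mirror padding (edge pixel not duplicated) gives every pixel,
including borders, a full patch without injecting artificial dark content;
patch centers cover every pixel at stride 1. Reflection is also used as the
convolution boundary, so constant images are exact fixed points of the
pre-filter.

**Intensity range.** All computation happens in floating point on the 0–255
scale without clipping; values are clipped and rounded (half-to-even) only
when an 8-bit image is written.

**Zero noise.** At `sigma = 0` the linked defaults degenerate gracefully: the
kernel approaches a delta, the bandwidth vanishes, and the filter becomes
the identity instead of erroring — only exact patch matches receive weight.

**Self-weight.** The self-candidate keeps its natural raw weight
$\exp(0) = 1$ without the capping some NLM implementations apply; cluster
restriction already bounds candidate dominance, and the uncapped choice is
what makes the closed-form weight examples exact.

## What the synthetic generator emulates — and what it does not

`make_phantom()` produces piecewise-smooth, anatomy-like scenes: a constant
background, elliptical hypo-/hyper-echoic lesions, and a smooth pseudo-random
texture field (white noise blurred to a speckle-scale correlation length,
scaled to a chosen amplitude). `add_noise()` provides additive zero-mean
Gaussian noise with standard deviation $\sigma \in \{10, 20, 50\}$ on the
0–255 scale — the degradation used by the replication experiments — and a
unit-mean log-normal multiplicative model (SD $\sigma/255$) reflecting the
multiplicative character of real speckle.

The generator does **not** simulate acoustic physics: no point-spread
function, no depth-dependent attenuation or time-gain compensation, no
Rayleigh envelope statistics, and no spatial correlation in the noise
itself. Consequently, passing tests demonstrate that the pipeline implements
its mathematical contract and improves fidelity under the stated degradation
models — they do not by themselves certify clinical image quality on real
scanner data.

The demonstration phantom (`example_phantom()`) uses a 120-gray background,
one hypo-echoic (−60) and one hyper-echoic (+70) elliptical lesion, and
texture of amplitude 12 gray levels — mid-range contrasts typical of
cyst-like and solid findings against tissue echotexture.

## Problem sizes used by the suite

Efficacy is measured on 128 × 128 phantoms across 20 noise seeds at
$\sigma = 20$; elementwise oracle equivalences run on 12 × 12 to 24 × 24
images where brute-force $O(N^2)$ references remain exact and fast; property
checks (Hu invariance, rotation recovery, weight normalization) use
15 × 15 patches, 100–1000 seeded cases. These sizes are the package's own
choices: large enough for the statistics to be stable, small enough that the
independent brute-force oracles — not the implementation under test — define
the expected values.

## Known limitations

- Cost scales with the sum of squared cluster sizes; a very large cluster
  (big homogeneous background) dominates runtime. `max_candidates` offers a
  deterministic cap, off by default because the uncapped procedure is the
  reference behavior.
- The mirror test is a sign comparison; for nearly symmetric patches
  $\phi_7 \approx 0$ and noise decides the sign. The frame then differs from
  the best alignment, but the distance penalty is small precisely because
  such patches are nearly symmetric.
- The $K \propto$ pixel-count heuristic transfers the reference setting
  (675 at 225 × 225) to other sizes; `k_sweep()` exists to tune $K$ per
  image class when quality matters more than the default.
- Rotation estimation is centroid-based only; patches whose centroid is
  short relative to the noise get unreliable angles. No exhaustive angle
  search is attempted, by design.
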