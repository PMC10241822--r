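---
title: "Small-neighborhood clustering segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-neighborhood clustering segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osnc)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the decisions
taken where the method family leaves genuine freedom. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The segmentation problem

The target imagery is surface inspection: a fixed grayscale camera over a
conveyor, bright convex products on a uniform background, and defects —
cracks, stains, breakages — that appear as localized gray-level anomalies
on the product surface. Segmentation must separate background, product and
defect quickly and reproducibly; downstream defect detection consumes the
mask. Two classical families frame the design: multilevel thresholding
(fast, but needs good thresholds and a segment count) and fuzzy c-means
clustering (robust, but iterative over every pixel and silent about the
number of clusters). The pipeline here uses cheap decimated-image
estimation to choose both the thresholds and the segment count, and an
attribute-space clustering step to resolve exactly the pixels thresholds
classify poorly.

## Attribute vectors

Each pixel is described by m attributes c_q(x), min-max normalized to
[0, 1] per image. The default set (m = 4) is the pixel gray level, the
3×3 local mean, the 3×3 local standard deviation, and the Sobel gradient
magnitude. The method family names a wider menu of candidate attributes
(peaks, valleys, tone, multimodality) without defining operators for them;
the four chosen here cover gray level, local brightness, texture contrast
and edge strength with standard, reproducible operators, and the list is
pluggable through `featureConfig()`. Borders use reflect padding so no
artificial edges appear at the frame. Per-image min-max normalization puts
all attributes on a common [0, 1] scale, which the chain radius ε and the
range-normalized distance below both rely on.

A consequence worth knowing: the spatial attributes (local mean, gradient)
take intermediate values along region boundaries, so pure attribute-space
clustering of a two-region image discovers a third, thin "edge" class.
That class is real structure, not an artifact; evaluations against
two-label ground truth should either use the gray attribute alone or
accept the boundary class costing its pixels after label mapping.

## Chain clustering and the range-normalized distance

Classes are discovered greedily: seed a class at the first unassigned
sample, repeatedly absorb the nearest unassigned sample within Euclidean
radius ε of the running class mean (recomputing the mean after each
absorption), stop when none qualifies, and repeat. Discovery is
deterministic given sample order (row-major pixel order; ties break to the
lowest index). The same chain growth run on one attribute at a time yields
the training weights ζ_q = s/L (the fraction of samples reachable in
attribute q) and, per class, the attribute weights b_q = max over classes
of the reachable member fraction. The b_q are renormalized to sum to 1 so
the classification distance is scale-stable; that renormalization is an
engineering addition, not part of the original update.

A sample is classified by

d_i(x) = Σ_q b_q |c_q(x) − V_i^q| / (O_iq^max − O_iq^min),

where the attribute range is taken over class i's members *together with
x* — so a query far outside the class inflates the denominator rather than
the distance, keeping d_i ≤ Σ b_q = 1. A zero range means the attribute is
constant and uninformative; its term contributes 0. Decision weights
λ_i = (1/(n−1))(1 − d_i/Σd) sum to 1 and rank classes inversely to
distance; the all-zero distance vector (every class equally perfect)
falls back to uniform weights.

Open choices resolved here: the "K nearest" samples entering the
single-attribute center V_l^q = (1/(K+1)) Σ_{j=l}^{l+K} c_q(x_j) are the
next K samples in index order, read literally from the marking
x_{l+1}, …, x_{l+K}; the neighborhood metric is Euclidean over the
normalized attributes; ε defaults to 0.1 in normalized feature space and
is exposed in the configuration, since the method family states no value.

## Center optimization and thresholds

On the gray-level domain the segmentation centers o_k minimize

B_f = Σ_k Σ_ij μ_k(L_ij)^r d_ijk², with Σ_k μ_k(L_ij) = 1,

by alternating the closed-form updates
o_k = Σ μ^r L / Σ μ^r and μ_k = d^(−2/(r−1)) / Σ_k d^(−2/(r−1)),
with d_ijk = |L_ij − o_k| (the gray domain is one-dimensional, so the
scalar absolute difference is the only shape-consistent metric). One
printed form of the center update carries exponent r in the numerator and
m in the denominator; the self-consistent form with r in both is
implemented, which is the standard fuzzy c-means fixed point. A pixel
coinciding with one or more centers takes membership 1/#coincident on
those centers and 0 elsewhere.

Defaults: r = 2 (the usual fuzzy exponent), convergence when
max |Δμ| < 10⁻⁵, at most 300 iterations. Initialization is deterministic
at the (k − 0.5)/n gray quantiles — reproducibility of iteration counts
matters more here than basin exploration, and a seeded random
initialization remains available behind `init = "random"`. When tied
quantiles would collapse two classes the duplicates are spread by a tiny
deterministic offset. A class that loses all membership weight (possible
only in pathological inputs) is re-seeded at a seeded random percentile
with a warning. The objective is non-increasing across iterations — the
standard alternating-minimization guarantee — and the suite checks it on
every fitted instance.

Thresholds interleave the sorted centers as J_c = β o_c + (1 − β) o_{c+1}
with β = 0.5, the customary midpoint; a pixel's label is the number of
thresholds strictly below its value, so a pixel exactly on a threshold
stays in the lower class.

## Choosing the sampling rate by entropy loss

Center fitting and segment-count selection only need the gray histogram's
shape, which survives decimation. Nearest-neighbor decimation at rate η
(output pixel (i, j) copies input pixel (⌊i/η⌋, ⌊j/η⌋); no interpolation,
so no new gray values) changes the Shannon entropy
S = −Σ p_k log₂ p_k of the 256-bin histogram; the relative loss
δ_η = |S₁ − S_η| / S₁ measures the distortion. Base-2 logarithms are used
throughout (the base cancels in δ_η anyway); a constant image has S₁ = 0
and δ := 0 by convention.

The variable-step search walks η from 0.5 with multiplicative steps —
down by t = ηk when δ < δ_min (still oversampled), up by t = η(1 − k/2)
when δ > δ_max — and accepts the first η whose loss lands in
[δ_min, δ_max]; the exact infimum is not needed. Defaults follow the
method's stated operating point: δ ∈ [0.01, 0.02], step factor k = 0.5,
at most 50 iterations. The upward step can overshoot 1; it is clamped and
halved on repeated overshoot so the search can re-enter the interval.
The accepted rate is finally clamped from below to S₀/min(M, N) with
S₀ = 32 px: the decimated short side must keep enough pixels for the
histogram to support peak counting. (The S₀ phrasing in the source
material is ambiguous; it is read here as a minimum decimated side
length.) The companion single-peak predicate `isUnimodal()` smooths the
histogram with a 5-bin moving average and counts local maxima whose
prominence exceeds ξ_h = 0.015 of total mass; the pipeline records the
verdict in its report — the method family never states how the flag feeds
back into the threshold count, so it is exposed as information rather
than wired into control flow.

## Validity: how many segments?

For each candidate count α the fitted partition is scored by fuzzy
correlation between classes:

δ_c² = Σ_ij μ_c² |L_ij − ν_c|²,  R_kl = Σ_ij μ_k μ_l |L_ij − ν_k||L_ij − ν_l|,
φ_kl = R_kl / (δ_k δ_l).

By Cauchy–Schwarz φ_kl ∈ [0, 1], with R_kk = δ_k² giving φ_kk = 1. Well
separated classes overlap little in membership, so their pairwise
correlations are small; an over-split cluster shares most of its mass
between two centers and drives φ toward 1. The criterion F(α) = max_{k≠l}
φ_kl is minimized over the candidate range (2–9 by default), smallest α
on ties. The membership matrix entering the criterion is the fuzzy
c-means fixed point for that α; the criterion is not re-optimized over U,
which is the natural reading of the joint minimum and keeps the sweep a
pure scoring pass. A degenerate class with δ_c = 0 yields φ = 0 with a
warning instead of failing the sweep.

## The pipeline and the hybrid refinement

`runOSNC()` orders the stages: rate search → decimation → validity sweep
on the decimated image → center fit at α* on the decimated image →
thresholding of the **full-resolution** image. Decimation influences only
parameter estimation; the emitted mask always has the input's size, since
inspection deployments consume full-size masks. A constant input image
short-circuits: the sweep would be meaningless, so the mask is a single
label and the report flags the degeneracy.

Thresholding misclassifies exactly the pixels whose gray values sit near
a threshold. In hybrid mode (the default) those pixels — within ±5 gray
levels of any threshold — are re-clustered in attribute space by chain
growth, and each discovered cluster is relabeled wholesale to the
threshold label the majority of its members already hold. The band
half-width of 5 levels is an interpretation of how the clustering and
thresholding stages combine; pure-threshold and pure-clustering modes are
both exposed (`mode = "threshold"`, `mode = "snc"`) so the two components
can be used and studied separately. By construction refinement can only
change pixels inside the band, and the suite checks that containment.

## The synthetic scene generator

The real imagery this method family targets is proprietary factory data,
so the package ships a generator instead of fixtures. `sceneSpec()` +
`generateScene()` emulate the essential structure: a uniform background
(default gray 40 — backgrounds are described only qualitatively in the
source material, so the level is a free parameter chosen dark), bright
disk-shaped objects (default gray 200, radius 15–25 px), three defect
phenotypes — crack: a 1–2 px random-walk curve inside an object; stain: a
darker filled ellipse; breakage: a disk bitten out of the boundary and
carved back to background — and additive Gaussian noise (default σ = 3
gray levels, a typical well-exposed camera noise figure), clipped to
[0, 255]. The truth mask (0 background, 1 object, 2 defect) is computed
before noise and is exact. Generation is a pure function of (spec, seed)
and restores the caller's RNG state.

What the generator does **not** emulate: illumination gradients and
vignetting, specular highlights on glossy surfaces, motion blur, textured
or cluttered backgrounds, object shapes beyond disks, and correlated
sensor noise. Tests passing on these scenes therefore demonstrate the
algorithmic properties (normalizations, convergence, recovery of well
separated gray populations, band-confined refinement) — not performance
on real factory imagery, which has to be assessed on real data.

## Problem sizes and numerical choices

The suite and the acceptance script run at desk scale, chosen so each
check completes in seconds while still exercising the full code path:
8×8 to 16×16 images for exact oracle comparisons (fuzzy c-means reference,
double-loop recomputations), 48×48 level-population images for validity
recovery over 10 seeds, 96×96 two-object defect scenes for end-to-end
accuracy over 6 seeds, and 96×96 to 256×256 smoothed-noise textures for
entropy-loss behavior over 20 seeds. Tolerances: membership and weight
normalizations to 1e-9; center agreement with the independent reference
to 1e-6 (both sides run to tight convergence; the reference is restarted
from its own output to squeeze out its looser internal stopping rule);
objective monotonicity with 1e-9 slack for floating-point accumulation.
Tie-breaks everywhere go to the lowest index so runs are bit-reproducible.

## Known limitations

- Chain clustering is O(L²) in the sample count; strides above 1 are the
  intended control on cost for large images.
- The validity sweep fits every candidate α, so its cost is the sum of
  the per-α fits; on the decimated image this is cheap, but sweeping on a
  full-resolution image defeats the purpose of the rate search.
- The entropy-loss criterion sees only the histogram: decimation that
  destroys thin structures (1 px cracks at η < 0.5) while preserving the
  histogram will pass unnoticed. That is precisely why thresholds are
  applied at full resolution and cracks remain detectable in the mask.
- One-dimensional gray-level clustering cannot separate classes with equal
  levels but different texture; that is the hybrid refinement's job, and
  fully texture-defined classes need `mode = "snc"`.
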