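---
title: "Methods: simulation, ridge-frequency normalization and matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, ridge-frequency normalization and matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantprint)
```

## Scope and model

`infantprint` implements a complete non-contact infant fingerprint
processing chain: a physics-motivated simulator with exact minutiae ground
truth, the preprocessing front end (flat-field correction, background
smoothing, bimodal contrast stretch), ridge-frequency normalization to a
fixed 8 px/ridge template space, oriented binarization with crossing-number
minutiae extraction, a local-descriptor rigid-consensus matcher, and
DET-based verification evaluation.

The central modelling idea is that infant and adult fingerprints differ
mainly in *scale*: ridge periods run from about 125 µm in newborns to about
450 µm in adults, so after resampling every image to the same
pixels-per-ridge density the same extraction and matching machinery applies
to all ages. All infant-specific difficulty is carried by the simulator
(fine periods, 4–5:1 ridge-to-valley width ratios, strong curvature of
5–10 mm fingers, peeling skin, optical artifacts of non-contact capture)
and by the acceptance-style campaigns that exercise the chain end to end.

## Simulator

### Ridge flow as distance-function phase fields

A phantom finger is a scalar phase field $\phi(x, y) = 2\pi\, g(x, y) /
\lambda$ rendered through a soft periodic pulse. The generator functions
$g$ are *exact distance functions* — distance to a far point (arch-like
flow), to a segment (loop-like), to a point (whorl-like), or to a line
(parallel gratings) — so $|\nabla g| = 1$ everywhere and the local ridge
period equals the generative period $\lambda$ exactly. This is what makes
period-accuracy claims testable to sub-pixel tolerances: the simulator's
period is not an estimate but an identity.

Minutiae are seeded as spiral phase singularities ($\pm \operatorname{atan2}$
terms added to the phase), which create exactly one ridge ending or
bifurcation each. Whether a singularity lands as an ending or a bifurcation
depends on the local ridge/valley parity, so ground-truth *type* and
*angle* are measured from an ideal noiseless patch: the analytic phase is
rendered at the normalized template scale (8 px/ridge), binarized at the
generative duty threshold, thinned, and scanned with the same
crossing-number code used by the real extractor. Ground truth therefore
follows exactly the conventions of the measurement chain, and localization
truth is exact.

Identity coordinates (minutiae positions, flow anchors) are stored in units
of the ridge period inside a ±8-period central box with a 3-period minimum
spacing. Identities are therefore scale-free: the same identity rendered at
125 µm and at 450 µm, or at different PPI, produces geometrically similar
patterns — which is precisely what ridge-frequency normalization is
supposed to undo, and what the growth model exploits.

### Morphometry defaults

Age presets fix the ridge period, finger diameter and peeling fraction
(newborn 137.5 µm / 5.5 mm / 0.15; neonate 200 µm / 6.5 mm / 0.10; infant
275 µm / 8 mm / 0.05; adult 450 µm / 12 mm / 0). Infant classes use a duty
cycle of 0.8 — ridges four times wider than valleys — so a 250 µm period
leaves a 50 µm valley, the feature that sets the resolution demands of the
whole problem (~7 px at 3400 PPI, hopeless at contact-scanner 500 PPI).

### Projection and artifacts

Curved fingers are produced by orthographic projection of the flat pattern
onto a cylinder: $x = R \sin(u/R)$, which compresses apparent periods by
$\cos\theta$ towards the silhouette and clips at 99.5% of the radius. The
truth structure carries the remapped minutiae, a per-block apparent-period
map and the tangent-angle map.

Artifacts model the failure modes of non-contact capture, applied in a
fixed order under seeded randomness: multiplicative illumination gradient,
a Gaussian-profile vertical halo band (saturating when strength ≥ 1),
elliptical peeling flakes (3–7 period diameter sheets carrying decorrelated
ridge texture, recorded in a truth mask), horizontal box motion blur, and
Gaussian DN noise, followed by clipping to the 12-bit range.

Default artifact strengths are the package's modelling choice for a
*final, optimized* acquisition device: sub-saturating halo (0.3), 2 px
motion blur (short-exposure regime), 30 DN noise, 0.25 illumination
gradient. Saturating halos and heavier degradation remain available and are
exercised in the test suite; they are simply not the default study
condition.

## Preprocessing

* **Flat-field correction** divides by a gain map and renormalizes to the
  foreground mean; zero-gain pixels are excluded from the mask with a
  warning.
* **Background smoothing** subtracts a Gaussian-smoothed background
  (σ = radius, default 24 px) and recenters at half the DN range. This
  removes residual low-frequency illumination while passing the ridge
  band.
* **Bimodal stretch** maps [noise floor, P99.5 of the foreground] linearly
  to an 8-bit range, expanding the valley/ridge separation; degenerate
  histograms are rejected rather than silently stretched.
* **Foreground segmentation** recovers a silhouette mask for maskless
  frames (image files carry no mask) from smoothed high-pass ridge energy:
  the finger is texture, the dark background is flat. Fully covered frames
  pass through unmasked.

Defaults (blur radius 24 px, noise floor 64 DN) are the values used by the
package's own evaluation campaigns; the parameter sweep demonstrates the
chosen cell against degenerate settings rather than asserting a universal
optimum.

## Ridge analysis and frequency normalization

Orientation is estimated per 16-px block by the squared-gradient method
($\theta = \tfrac12 \operatorname{atan2}(2 G_{xy}, G_{xx} - G_{yy}) +
\pi/2$) with gradient-anisotropy coherence; incoherent blocks are invalid.
The local period is measured by sampling an intensity profile perpendicular
to the block orientation, detrending, Hann-windowing, zero-padding the FFT
8×, and interpolating the dominant log-power peak parabolically within a
4–80 px band; the global period is the coherence-weighted median of block
periods.

Normalization rescales the image by `8 / global_period`. Minification is
preceded by a Gaussian anti-alias filter (σ = 0.6·√(1/s² − 1));
interpolation is bilinear in both directions. (A cubic kernel for
magnification was considered; the available resize primitive offers
bilinear only, and the measured normalized period is unaffected at the
±0.5 px tolerance, so bilinear is used throughout.) The output period is
re-measured and reported — the package treats "what period did we actually
land on" as a first-class quantity.

## Binarization, skeletonization, minutiae

The normalized image is smoothed by a bank of 12 anisotropic Gaussians
(σ 3 along the ridge, 0.7 across) steered by the block orientation field,
then thresholded at the midpoint between the local mean and the local
envelope midrange — a rule that *preserves the duty cycle* instead of
forcing 50% ridge coverage, essential at 4:1 ridge:valley ratios where the
valley is ~1.6 px wide. Diagonal one-pixel valley bridges are broken
explicitly, since 8-connected ridges otherwise fuse across them. A quality
mask excludes clustered blocks with no coherent orientation or with a
ridge period outside the expected band (noise, saturated or structureless
patches, background).

Skeletonization is Zhang–Suen thinning (vectorized, with a 2×2-block
cleanup pass that deletes simple pixels only), followed by spur pruning.
Minutiae are crossing-number features: CN 1 endings, CN 3 bifurcations.
Ending angles come from tracing the ridge; bifurcation angles from the
nearest valley ending in the dual (valley) skeleton, path-averaged and
bearing-checked; both are snapped to the block orientation modulo π,
keeping the measured half-plane. Filters: border exclusion (8 px from the
mask edge), close-pair resolution (keep the better-quality of two within
4 px), density clusters and anti-parallel same-type pairs dropped, quality
floor 0.3, at most 40 minutiae by quality. Templates serialize to JSON and
round-trip bit-exactly.

## Matching

Each minutia gets a rotation/translation-invariant descriptor from its
k = 5 nearest neighbours (distance, relative bearing, relative angle).
Candidate correspondences (exhaustive when |A|·|B| ≤ 2500) vote for rigid
transforms; consensus clusters in a 15°/12 px window are shortlisted
(top 10), each refined by an iterated tight-inlier rigid fit (60% of the
mate tolerance) and finally mated greedily at 8 px / 30°. The score is
`n_mated / max(min(|A|, |B|), 8)` — the floor damps small-template
self-matches — and matching is symmetric.

Two admissibility bounds are package design choices justified by the
acquisition geometry (upright fingers centred in an aperture): rotation
≤ 60° and template-centroid displacement ≤ 40 px. They reject
physically impossible alignments that small minutiae sets can otherwise
vote into existence. The matcher refuses templates whose resolution is not
8 ± 0.5 px/ridge rather than silently comparing incompatible spaces.

## Evaluation

`det_curve` enumerates every observed score as a threshold with the
convention FAR(t) = fraction of impostor scores ≥ t, FRR(t) = fraction of
genuine scores < t (ties accept), and interpolates the EER linearly;
`tar_at_far` reports the best TAR over thresholds meeting the FAR budget.
The DET implementation is tested against a brute-force counting oracle.
`fuse_multifinger` implements max-rule fusion.

`run_campaign` generates a seeded phantom population (all randomness via a
counter scheme from one master seed, so sweeps re-use identical images),
renders each identity with independent pose (±15°) and artifact draws,
applies a similarity growth model between impressions (period × growth
with the rendered diameter scaled to match, so growth is a true rescaling,
not a distortion), and scores all genuine plus sampled impostor pairs.
Campaign problem sizes are desk-scale package choices: the end-to-end
benchmark uses 50 identities × 2 impressions at 1500 PPI; age-ordering
campaigns 15 identities at 2000 PPI; the sweep 8 identities over 3 cells.

## Known limitations

* At duty 0.8 the valley is ~1.6 px wide in template space; extraction on
  clean phantoms recovers ≥ 80% of seeded minutiae but whorl-family cores
  remain the weakest flows, and bifurcation angles inherit valley-skeleton
  noise. This is the binding constraint on end-to-end campaign TAR.
* The cylinder projection corrects geometry only globally: normalization
  rescales by one global period, so foreshortened silhouette regions stay
  locally compressed and are handled by exclusion (quality mask) rather
  than unwarping.
* Peeling flakes whose displaced texture keeps the ridge period are
  locally indistinguishable from genuine ridge flow, so the quality mask
  does not exclude them; their false features are left to the extraction
  filters and to match consensus. Only structureless or off-period
  degradation is masked out.
* Growth between impressions is modelled as pure similarity scaling;
  real growth is mildly anisotropic.
* The simulator's optics are parametric (Gaussian halo, box blur); they
  reproduce failure modes, not a full physical light-transport model.
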