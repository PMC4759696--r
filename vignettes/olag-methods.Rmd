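---
title: "Mapping lymphatic and blood vessels in skin OCT: methods and design"
author: "olagr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lymphatic and blood vessels in skin OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The two contrast mechanisms

Volumetric OCT of skin carries two independent vascular signals.

**Blood vessels** move. When the same cross-sectional B-frame is acquired
repeatedly at one slow-axis location, red blood cells decorrelate the complex
OCT signal between repeats (dynamic speckle), while static tissue returns a
nearly constant value. Optical microangiography (OMAG) turns this into flow
contrast with the mean absolute adjacent difference over $R$ registered
repeats:

$$\mathrm{flow}(z,x) = \frac{1}{R-1}\sum_{i=1}^{R-1}
  \left| C_{i+1}(z,x) - C_i(z,x) \right|,$$

where $C_i$ is the complex signal of repeat $i$ (the modulus is used
verbatim for amplitude-only data). The statistic is invariant to a global
phase rotation and is identically zero for noise-free static input. For
static voxels carrying additive circular complex noise of per-quadrature
standard deviation $\sigma$, the adjacent difference is Rayleigh with scale
$\sigma\sqrt{2}$, so the expected flow floor is $\sigma\sqrt{\pi}$ — this
closed form is used as a Monte-Carlo oracle in the tests.

**Lymphatic vessels** do not scatter. Lymph is nearly transparent at OCT
wavelengths, so lymphatic lumens appear as low-scattering (dark) tubes in
the dermis. They are extracted from the *structural* image by the OCT-based
lymphangiography (OLAG) chain: attenuation compensation, layer segmentation,
flattening, per-slice histogram equalization, and a sorted minimum intensity
projection (sMIP) over depth slabs of the dermis.

## The OLAG chain, step by step

**Attenuation compensation.** Light attenuates roughly exponentially with
depth, so raw intensities cannot be thresholded globally. Each A-line is
renormalized by its remaining tail energy (inclusive of the current pixel),
after raising intensities to an exponent $n$ (default 2) for contrast:

$$A(z) = \frac{I(z)^n}{2\sum_{u \ge z} I(u)^n}.$$

The inclusive tail bounds the output to $[0, 0.5]$ with no division hazard;
the deepest nonzero pixel of every A-line maps to exactly $0.5$. For a pure
exponential $I(z) = I_0 e^{-\alpha z}$ sampled at pitch $\Delta$, the
geometric series gives a constant compensated value
$(1 - e^{-n\alpha\Delta})/2$ away from the bottom boundary, which the test
suite checks to 1%. (The exclusive-tail variant would give
$(e^{n\alpha\Delta} - 1)/2$; the two agree to first order in
$n\alpha\Delta$, and the bounded inclusive form is used throughout.)
All-zero A-lines are returned as zeros and flagged rather than erroring.

**Surface and epidermal–dermal junction (EDJ).** The tissue surface is the
first depth at which the axially smoothed amplitude exceeds a noise
threshold (median + 6 MAD of the top-of-volume noise region); the crossing
is then snapped to the raw-amplitude crossing within the smoothing
half-window, because a centered moving average biases the detected edge
shallow by up to half the window. The EDJ is found per column with a
step-matched filter: the depth maximizing mean intensity just above minus
just below (3 voxels each side, after 3×3 lateral box averaging), searched
40–300 µm below the surface. A plain gradient of a boxcar-smoothed profile
was rejected because its response to a step is a plateau, which leaves the
argmin ambiguous under speckle; the matched filter peaks at the junction
voxel. Columns whose peak response does not exceed 4× the median absolute
response in their search window are flagged (no epidermis contrast) and
filled from neighbours; both maps are median-filtered laterally.

**Flattening and slabs.** The dermal slabs quoted in depth "of dermis"
follow the layer, so the volume is flattened to the EDJ (pure integer
A-line shifts, with vacated voxels tracked as invalid and excluded from all
later statistics; flattening is exactly invertible on the valid region).
Default slabs are $[0,200)$, $[200,400)$ and $[400,600)$ µm below the EDJ.

**Equalization and sMIP.** Each en-face slice is globally rank-equalized
over its valid pixels (empirical CDF, ties averaged) — a probability
integral transform that gives a uniform $[0,1]$ output, preserves rank
order and is idempotent on continuous data. The sMIP then averages, per
(x, y) column, the $k$ smallest equalized values in the slab. $k = 1$
reduces to a minimum projection and $k$ = slab thickness to a mean
projection, which the tests verify bit-for-bit against brute-force oracles.

**Choice of k.** The default is $k = 20\%$ of the slab thickness in voxels
(minimum 1). This is an order-statistics compromise: with $m$ speckle
samples per column, the average of the $k$ smallest uniforms concentrates
near $k/(2m)$ with spread shrinking in $k$, so too small a $k$ (e.g. 2 of
25) leaves the background minima statistically overlapping genuine lumen
values and no threshold separates them; too large a $k$ dilutes lumens that
fill only part of the slab. Dermal lymphatic lumens at this scale have
diameters of roughly 100–150 µm against 200-µm slabs, so averaging the
darkest ~20–25% of the slab keeps lumens dark while pulling speckle minima
toward the bulk. The fraction is exposed in the configuration
(`olag$k_frac`).

**Mask threshold.** The default threshold is Otsu computed on the
*log-intensity* of the sMIP map. Lymph vessels occupy only a few percent of
the field, and under that class imbalance Otsu on the linear histogram
maximizes between-class variance by splitting the broad tissue mode rather
than isolating the small dark mode (measured mask fractions of ~60% on
phantom data). Lumen-to-tissue contrast is multiplicative, so in the log
domain the lumen mode sits far from the tissue mode and the same criterion
locks onto the true valley. A fixed-percentile rule is available, but note
it pins the detected density by construction and is therefore unsuitable
for longitudinal density monitoring. Components smaller than 10 pixels are
discarded; an optional elongation filter (moment-based major-axis length
over equivalent circular diameter, default ratio 1.8) removes compact
edema-like blobs, approximating the "not part of the connected network"
criterion used to reject edema by eye.

**Registration.** Bulk axial tissue motion between repeats is removed by
global integer-voxel shifts maximizing the normalized cross-correlation of
each repeat's amplitude against the first, over an exhaustive
$\pm n_z/4$ search. Integer shifts keep the operator exactly invertible, so
recovery of injected shifts can be asserted exactly; sub-pixel motion is out
of scope. Rows vacated by any shift are excluded from downstream statistics.

**Projections and mosaicking.** The angiogram is smoothed per en-face plane
with a normalized 3×3 Gaussian ($\sigma = 0.8$ voxels, reflective borders,
sum-preserving), then collapsed by maximum intensity projection; the
depth-encoded MIP records the argmax depth with ties resolved to the
shallowest voxel for determinism. Wide fields are assembled by placing
tiles at nominal grid positions, refining each by cross-correlation within
± the seam overlap (the nominal position wins degenerate or tied
correlations), and linearly feathering the overlaps — nine 3 mm tiles with
0.5 mm seams yield an 8 mm × 8 mm field.

**Densities.** Vessel density is the area fraction of en-face pixels
classified as vessel, in percent of the valid field (the standard OCTA
convention; the normalization is recorded in each report). Dice overlap
$2|A \cap B| / (|A| + |B|)$ validates masks against ground truth, with
both-empty defined as 1 (agreement) and flagged.

## The synthetic skin phantom

There are no public repeated-B-frame OCT datasets of human skin with
lymphatic ground truth, so every stage is validated against a generated
phantom whose truth is known by construction:

- **Speckle**: fully developed — each voxel draws an independent complex
  circular-Gaussian field (Rayleigh amplitude), scaled by a reflectivity
  map: air above the (optionally sinusoidal) surface, an epidermis 120 µm
  thick at 2× dermis amplitude, dermis below.
- **Attenuation**: amplitude decays as $e^{-\mu d}$ ($e^{-2\mu d}$ in
  intensity) with $d$ the depth below the *local* surface; default
  $\mu = 1.5\,\mathrm{mm^{-1}}$, typical of dermis at 1300 nm.
- **Lymph lumens**: capsule-shaped tubes (polyline centerlines, exact
  point-to-segment distance in µm, so cross-sections stay circular under
  the 8 µm axial / 20 µm lateral pitch) with amplitude scaled to 0.1 of
  dermis. Defaults place one lumen per 200-µm slab, deeper ones larger, as
  in skin.
- **Blood vessels**: tubes whose voxels are redrawn independently every
  repeat (a decorrelation fraction mixes old and new fields; 1 = fully
  fresh). Static voxels are bit-identical across repeats before noise.
- **Bulk motion**: optional global integer axial shift per B-frame.
- **Noise**: additive complex noise of per-quadrature $\sigma = 0.02$
  (≈ −34 dB against unattenuated dermis, a high-SNR acquisition).

The default grid is 128 × 128 × 128 voxels × 8 repeats (≈ 1 mm depth,
2.56 mm field), small enough that generation plus the full pipeline runs in
well under a minute per volume; unit tests use 96 × 48 × 48 × 4 variants.
The phantom deliberately does **not** model wave-optics propagation,
multiple scattering, birefringence, flow-speed-dependent decorrelation,
hair follicles, or vessel networks with branching topology. Passing the
phantom therefore demonstrates that the chain recovers dark tubes and
decorrelating voxels under realistic speckle, attenuation, layer geometry
and motion — not that it meets clinical accuracy on human skin, where
follicles (strong absorbers) are a known false-positive source and edema
can mimic lumens.

## Degenerate inputs and tie-breaks

All-zero A-lines, all-noise volumes (no surface), contrast-free epidermis,
constant en-face slices, constant angiogram projections and empty masks are
each handled by flagging rather than failure, and flagged columns/pixels
are excluded from statistics or filled from neighbours where a value is
geometrically required. Argmax ties resolve shallow; tied mosaic
correlations resolve to the nominal tile position; both-empty Dice is 1.
All randomness in a pipeline run flows from the single configured seed into
the phantom generator; every analysis stage is deterministic, which is what
makes byte-identical reruns (checked via per-output MD5 in the provenance
record) possible.

## Known limitations

- Registration is global and axial-only; lateral or rotational motion is
  not corrected.
- The sMIP/threshold defaults were chosen against the phantom's speckle
  statistics; heavily textured real dermis may need the exposed `k_frac`,
  threshold method and `min_size` adjusted.
- Lymph masks are 2D per slab, as in the original en-face presentation; no
  3D lumen segmentation or network topology analysis is attempted.
- Vessel density is an area fraction and inherits every upstream
  segmentation bias; absolute values should only be compared within a
  fixed parameter set (the provenance record exists for exactly this
  reason).
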