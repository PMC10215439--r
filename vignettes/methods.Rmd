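---
title: "Methods: wall shear stress indices and thrombus co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall shear stress indices and thrombus co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iltwss)
```

## Scope and model

`iltwss` is a post-processing toolkit for pulsatile hemodynamics on the
luminal surface of abdominal aortic aneurysms (AAA). Its inputs are the
products of an upstream CFD simulation and of medical-image segmentation: a
triangulated lumen surface, a per-vertex wall shear stress (WSS) vector time
series over one cardiac cycle, and an outer intraluminal-thrombus (ILT)
surface. The CFD solve itself is out of scope; the package instead ships a
synthetic generator that produces surface WSS fields with closed-form
ground truth, which is what makes the whole index suite verifiable.

Given the WSS series $\vec\tau(t)$ at a vertex with outward unit normal
$\hat n$, over a cycle of period $T$, the package computes:

- **TAWSS** $= \frac{1}{T}\int_0^T \lVert\vec\tau\rVert\,dt$ (Pa) — mean
  shear loading.
- **OSI** $= \frac12\left(1 -
  \frac{\lVert\frac{1}{T}\int_0^T \vec\tau\,dt\rVert}{\mathrm{TAWSS}}\right)$
  — directional oscillation, 0 (unidirectional) to 0.5 (zero cycle-mean).
- **TransWSS** $= \frac{1}{T}\int_0^T \left|\vec\tau\cdot\left(\hat n\times
  \hat e_{mean}\right)\right| dt$ (Pa), with $\hat e_{mean}$ the cycle-mean
  WSS direction — multidirectionality transverse to the dominant direction.
  **NTransWSS** divides it by its maximum over the region of interest.
- **RRT** $= \left[(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}\right]^{-1}$
  (Pa$^{-1}$) — note the denominator is exactly the cycle-mean vector
  magnitude, an identity the test suite checks to $10^{-9}$.
- **ECAP** $= \mathrm{OSI}/\mathrm{TAWSS}$ (Pa$^{-1}$) — high where shear is
  simultaneously low and oscillatory, i.e. thrombogenically favorable.

Two published renderings of OSI divide a time *integral* (Pa·s) by a time
*average* (Pa); that form is dimensionally inconsistent and cannot reach
the documented 0–0.5 range. We implement the standard time-averaged-numerator
(Ku-type) definition, and the analogous $1/T$ prefactor for TransWSS, which
reproduce the documented bounds exactly.

ILT thickness is estimated per lumen vertex as the minimum Euclidean
distance to the outer ILT surface, minus a constant 2 mm wall mask (the
in vivo AAA wall ranges roughly 1–4.3 mm; 2 mm is the conventional constant
assumption), clamped at zero. Distances default to the outer *vertex set*
(matching the point-cloud procedure used with densely sampled segmentations);
an exact point-to-triangle mode is available for coarse outer meshes and is
never larger than the vertex-mode distance.

## Numerical choices

**Quadrature.** Cycle integrals use the periodic trapezoidal rule: samples
$t_1 < \dots < t_K \in [0,T)$ are closed by wrapping the first sample, so
weights sum exactly to $T$ and sampling need not be uniform. For
band-limited fields the error decays as $O(K^{-2})$; for rectified
sinusoids (which have kinks) the observed error at $K = 360$ is a few
times $10^{-5}$ relative — comfortably below the 1% recovery target used
in validation.

**Tangency.** WSS is by definition tangential. Input vectors are projected
onto the local tangent plane before TransWSS; a component along $\hat n$
exceeding 5% of the local magnitude anywhere raises a data-quality warning
at construction.

**Degeneracy policy.** Vertices where TAWSS falls below $10^{-6}$ Pa, or
where the cycle-mean vector is below $10^{-9}$ Pa (no defined mean
direction), are *flagged* and given capped or zero values — RRT and ECAP
cap at $10^6$ Pa$^{-1}$, TransWSS is set to 0 — rather than NaN, so every
downstream statistic remains computable. All floors and caps live in
`index_config()` and are echoed into the pipeline provenance block.

**Normals.** Vertex normals are area-weighted averages of incident-face
normals (the unnormalized cross product is twice the face area, so summing
it gives the weighting for free), with outward orientation required from
the face winding; closed meshes are checked via signed volume. The
synthetic generator uses exact analytic normals of its surface of
revolution, so generator fields are tangent to machine precision.

**Thresholds and units.** Coordinates and thickness are millimetres
throughout; the clinically quoted thickness cut-offs are in centimetres
(thickest ILT $\ge 1.7$ cm, thinnest $\le 0.15$ cm, alternatives 1.5/0.3)
and are converted in exactly one place (`extreme_ilt_regions()`) to avoid
silent 10× errors. Hemodynamic cut-offs follow the common literature
values: TAWSS $< 0.4$ Pa, OSI $> 0.2$ (0.3 as alternative), ECAP $> 1.4$
Pa$^{-1}$, RRT $> 10$ Pa$^{-1}$. Two thresholds have no literature
consensus and are package choices, recorded in every report: ILT presence
above 0.1 mm (sub-voxel thickness at 1–2 mm CT slice spacing is
segmentation noise), and an NTransWSS high/low split at 0.5.

**Statistics.** Box-plot summaries use type-7 (linear interpolation)
quantiles with 10th/90th-percentile whiskers. Spearman's $\rho$ is the
average-rank Pearson correlation (base R `cor(..., method = "spearman")`),
with a two-sided large-sample $t$ approximation for $p$; correlations with
ILT thickness are computed over the ILT vertex set. Spatial autocorrelation
between neighboring vertices is deliberately ignored, as is conventional in
this literature — the $p$-values are therefore anti-conservative and should
be read as descriptive, not inferential.

**Grid convergence.** The verification module implements Roache's
three-grid Grid Convergence Index with safety factor 1.25: observed order
$p = \ln|(f_c - f_m)/(f_m - f_f)|/\ln r$, fine-grid
$\mathrm{GCI} = F_s\,|(f_m-f_f)/f_f|/(r^p-1)$, plus the asymptotic-range
ratio. Oscillatory or stalled triplets are flagged and refuse to report an
order rather than producing a misleading one.

## The synthetic scenario

The generator emulates the segmentation + CFD products on an idealized
fusiform aneurysm: a tube of radius 10 mm with a Gaussian bulge
($\Delta R = 15$ mm, $\sigma = 15$ mm, centered at $z_0 = 60$ mm of a
120 mm segment), a 1.0 s cardiac cycle, and per-vertex WSS
$\vec\tau(t) = (m + a\cos\omega t)\,\hat e_{ax} + b\sin(\omega t)\,\hat
e_{circ}$ in the local tangent frame. Every vertex belongs to one of three
exact regimes, so closed forms exist everywhere:

| regime | parameters | TAWSS | OSI | TransWSS |
|---|---|---|---|---|
| steady | $b=0$, $a \le m$ | $m$ | 0 | 0 |
| oscillatory | $m=b=0$ | $\frac{2}{\pi}a$ | 0.5 | undefined (flagged) |
| transverse | $a=0$, $m,b>0$ | — | — | $\frac{2}{\pi}b$ |

The default scenario places a purely oscillatory, low-magnitude patch on
the posterior sac wall (where slow recirculating near-wall flow is
expected), a steady-plus-transverse patch anteriorly, and steady 1.2 Pa
shear elsewhere, dipping smoothly inside the sac. The ground-truth ILT is a
Gaussian bump peaking at 19 mm, co-located with the posterior oscillatory
patch and truncated to exactly zero in the far field, plus a 2 mm wall
offset along the vertex normals. This construction reproduces the
qualitative clinical contrast the regional statistics are meant to detect:
thick thrombus over low-TAWSS/high-OSI wall, thin or absent thrombus where
shear is high and unidirectional — so the report's favorable-fraction
ordering and the signs of the thickness–index correlations are predictable
and tested.

Magnitudes vary smoothly *within* each regime but regime boundaries are
sharp; a real CFD field has no such seams. Other realism limits: no jet
impingement or vortex structures, no bifurcated iliac geometry, a
rotationally clean sac, and offset-constructed (rather than independently
segmented) outer surfaces. Passing the recovery tests therefore validates
the *post-processing arithmetic* — quadrature, frames, distances, masks,
statistics — not the hemodynamic realism of any CFD model.

Two geometric caveats bound the thickness validation. Offsetting a surface
along its normals only yields a minimum distance equal to the offset where
the offset field varies slowly: on steep bump flanks the nearest point of
the outer surface genuinely is closer than the local offset, so recovery
is asserted at the (flat) apex neighborhood, on uniform offsets, and on
concentric spheres. And outward offsets can self-intersect where the
surface is concave along the offset direction; the generator warns when
the offset exceeds the local axial curvature radius on concave shoulders.

## Problem sizes and verification suite

Default validation sizes are chosen to keep closed-form error well below
the asserted tolerances: 360 time samples per cycle and a 64 × 160 surface
grid (10,240 vertices) for index recovery within 1%; 40 × 80 UV spheres
(3,042 vertices) for the concentric-distance check; meshes of at most 500
vertices for exact agreement between the compiled distance kernel and a
pure-R exhaustive oracle (to $10^{-12}$, the difference being summation
order); 1,024 random band-limited vertex histories for the OSI bounds,
TransWSS $\le$ TAWSS, and RRT identity properties. The pipeline determinism
check runs the full synthetic workflow twice into separate directories and
compares every output file byte for byte; for that reason reports carry no
timestamps and the provenance block echoes the complete effective
configuration (thresholds, floors, spec, seed) with no hidden defaults.

## Known limitations

- Vertex-mode distances carry a discretization bias of order the outer
  mesh edge length; use triangle mode for coarse outer surfaces.
- The wall mask is constant (2 mm default); real AAA wall thickness varies
  regionally.
- Surfaces must be pre-aligned in one frame; no registration is performed.
- The on-disk WSS series format is long CSV; very long series are better
  generated in memory than round-tripped through text.
- $p$-values ignore spatial autocorrelation (see above).
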