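---
title: "Quantifying mycorrhizal network architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycorrhizal network architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myconet)
```

## The problem

Arbuscular mycorrhizal fungi (AMF) build extraradical hyphal networks —
filamentous webs of hyphae outside the root — whose architecture governs how
efficiently they forage for and transport nutrients such as phosphorus.
Experiments that grow two host roots on a shared plate, bridged by a
fungus-only central compartment, produce micrographs of these networks plus
tabular assay data: qPCR copy numbers as a proxy for fungal biomass, and
fluorescence of quantum-dot-labelled apatite as a traceable phosphorus
source. `myconet` turns those raw materials into a small set of quantitative
descriptors:

* **surface density** — the fraction of the field covered by hyphae;
* **mass fractal dimension** \(D_m\) — the space-filling complexity of the
  network, from the box-counting scaling law \(N(s) \propto s^{-D_m}\);
* **spatial gradient profiles** of both, across ordered regions of interest
  (ROIs) running from the compartment barrier towards the centre;
* **copy-number → biomass calibration** and **transfer efficiency** —
  quantum-dot signal delivered to the focal root per mg of focal
  extraradical hyphae.

## Image-processing chain

Each micrograph passes through four stages, every one a separate exported
function so intermediate rasters can be inspected:

1. `binarize()` — Otsu's threshold by default (via EBImage), a fixed
   threshold as override, with an `invert` flag for dark-hyphae-on-bright
   polarity. Already-binary inputs pass through unchanged, so the operation
   is idempotent.
2. `clean_mask()` — optional morphological closing with a disc (radius in
   px; 0 = off), then removal of connected components smaller than
   `min_cluster_px`. Specks of camera noise are isolated and tiny; hyphal
   strands are long and connected, so a size threshold separates them
   cleanly. The default of 20 px at the canonical 7.8125 µm/px scale
   (a 5 × 5 mm field at 640 × 640 px) is a documented tunable, not a
   measured constant. Connectivity defaults to 8 because 1-px-wide diagonal
   strands are common in thinned or faint hyphae; `EBImage::bwlabel` is
   4-connectivity only, so labelling runs on the pixel adjacency graph via
   igraph for either setting.
3. `skeletonize()` — Zhang–Suen thinning to a one-pixel-wide centreline.
   No installed R package provides binary thinning, so the two-subpass
   algorithm is implemented here, vectorized over whole-image neighbour
   shifts. Termination is "no pixel deletable", which makes the operation
   exactly idempotent; deletion-only updates guarantee the skeleton is a
   subset of its input.
4. `extract_rois()` — 0-based, half-open square crops with position labels
   ordered barrier → centre; the pixel scale is propagated.

With smoothing off, the chain is monotone by construction:
skeleton ⊆ clean ⊆ binarized foreground.

## Box counting and the dimension fit

`box_count()` partitions the raster into an axis-aligned grid of s × s
boxes and counts boxes containing any foreground. Partial edge boxes count
like ordinary boxes; for the canonical 640-px ROI and the default grid
sizes {8, 16, 32, 64} there are none. The default grid set spans the
standard 8–64 px range geometrically — four points, evenly spaced in log s,
which is what an unweighted log–log fit wants; intermediate sizes add
little information and correlate strongly.

`estimate_dimension()` fits \(\log N(s)\) on \(\log s\) by ordinary least
squares (natural logs) and reports \(D_m = -\text{slope}\), the intercept,
and \(r^2\). Grid sizes with \(N(s) = 0\) carry no information and are
dropped with a warning rather than failing the ROI; fewer than two usable
points is an error because the slope is undefined. For a constant curve
(a single foreground pixel, \(N \equiv 1\)) the fitted slope is exactly 0
and \(r^2\) is reported as `NA`, since there is no variance to explain.
Estimates outside \([-0.1, 2.1]\) are flagged, not rejected: fit noise can
push a legitimate estimate slightly past the theoretical \([0, 2]\) range.

Grid anchoring is top-left by default — reproducibility first. The optional
`anchor` argument aligns the grid to any of the four ROI corners; averaging
over the four anchors gives a robustness check. When every grid size
divides the ROI side the four anchors coincide and the choice is moot; it
matters only for non-divisor grids.

Box counting defaults to the **skeleton** rather than the cleaned mask:
the skeleton captures network topology independent of strand thickness, so
\(D_m\) measures branching architecture rather than hyphal width. Counting
the cleaned mask instead is one configuration flag away
(`source = "clean_mask"`), and is the right choice for rasters that *are*
the object of interest, such as the analytic fixtures below. Density is
always measured on the cleaned mask, since it is defined as the surface
occupied by the network.

## The synthetic generator: what it emulates, and what not

No public generative model exists for these networks, so validation runs on
a purpose-built simulator (`generate_network()`). Hyphal tips enter from
the field edges and advance as correlated random walks: per step the
heading gets Gaussian jitter (`angle_jitter_rad`, default 0.3 rad), the tip
advances `step_len_px` (4 px), may bifurcate with probability
`branch_prob` (0.05), and, on landing on an existing strand, terminates
with probability `fusion_prob` (0.5) — an anastomosis analogue. Strands are
Bresenham lines dilated to `strand_width_px` (2 px). Growth halts at
`target_coverage_frac` (default 0.06, the middle of the few-percent
coverages typical of sparse extraradical networks; gradient presets use
0.04–0.08) or when all tips have terminated, in which case the image is
returned with `target_reached = FALSE` rather than an error. Salt noise
(`noise_speckle_frac`, default 0.002) is applied after growth so the
cleaning stage can be exercised against the noise-free ground truth, which
is attached to the image metadata along with realized coverage, centreline
length and branch count.

The generator reproduces the *statistical* features the estimators care
about — sparse curvilinear foreground, branching topology, tunable density
gradients, known coverage — and nothing else. It does not model nutrient
flow, 3D growth, hyphal death, or the optics of a real microscope
(uneven illumination, blur, out-of-focus mycelium). Tests passing on
synthetic images therefore demonstrate that the estimators are correct and
robust on filamentous masks with known truth; they do not certify
segmentation quality on any particular real micrograph.

Determinism is part of the contract: the generator runs under a private
RNG stream seeded from `rng_seed` and restores the caller's RNG state, so
identical parameters give bit-identical rasters. A gradient series derives
one seed per location from the base seed.

## Analytic fixtures

Four exact rasters pin the estimator to closed forms
(`make_fixture()`): the filled square (\(D_m = 2\)), a 1-px line
(\(D_m = 1\)), a single pixel (\(D_m = 0\)), and the depth-6 Sierpinski
carpet (729 × 729, \(D_m = \log 8 / \log 3 \approx 1.8928\), coverage
\((8/9)^6\)). Under power-of-3 aligned grids the carpet's box counts are
exactly \(N(3^j) = 8^{6-j}\), so the log–log fit recovers the dimension to
machine precision — a rare case where a fractal estimator has an exact
oracle.

## Assays

`fit_calibration()` regresses dry biomass (mg) on qPCR copy number per
strain, by ordinary least squares with a free intercept by default. The
wet-lab line this mirrors subsamples 0.5–5 mg of fungal material, so
simulations use that range. A zero intercept is defensible biologically
(zero copies, zero biomass) but the free intercept absorbs extraction and
amplification offsets; `through_origin = TRUE` switches. Negative biomass
predictions at low copy numbers are clamped to zero with a warning flag.
Unfittable strains (fewer than two samples, or zero-variance copy numbers)
are reported and skipped while the rest proceed.

`transfer_efficiency()` is exact arithmetic: quantum-dot signal in the
total focal root divided by focal extraradical biomass, the sum of fungal
biomass in the focal compartment and focal-strain biomass in the central
compartment. Only the sum enters, so the split between compartments cannot
affect the result — a property the tests assert. When two strains are too
genetically similar for qPCR to distinguish (as with the near-identical
strain pair in the motivating system), all central-compartment biomass is
attributed to the focal strain; the pipeline logs this attribution
prominently rather than silently assuming it.

Fluorescence units are relative. No conversion to absolute phosphorus is
attempted; efficiencies compare treatments, not absolute fluxes.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with top-left origin; ROIs are
  half-open intervals. Binary rasters are integer 0/1 matrices.
* Otsu on a constant image is an error (no threshold exists); binarizing an
  already-binary image is the identity.
* An empty mask cleans to empty and skeletonizes to empty; a generator run
  with `n_seeds = 0` returns an empty image with coverage 0.
* Realized generator coverage overshoots its target by at most one growth
  step (≈ `step_len_px · (strand_width_px + 2)` pixels).
* The log–log fit uses natural logarithms; base only shifts the intercept.

## Problem sizes

The property suites (foreground nesting, noise recovery, gradient shapes)
run the generator at 320 × 320 px — the study's coverage range and strand
geometry on a quarter-size raster — which keeps many-seed loops cheap while
leaving every estimator code path identical; single-image tests and the
fixtures run at the canonical 640 × 640 (and 729 × 729 for the carpet).
Gradient checks average 20 seeds; oracle equivalence uses 1000 random
64 × 64 masks; calibration recovery uses 100 simulated sets of n = 20.

## Known limitations

* Zhang–Suen thinning can erase degenerate 2 × 2 blobs entirely; real
  cleaned networks (components above `min_cluster_px`) are unaffected, and
  the topology-preservation tests run on such masks.
* \(D_m\) from four grid sizes has non-trivial variance on sparse masks;
  the `r_squared` diagnostic and the `anchor` robustness mode exist to
  catch poorly determined fits.
* The qualitative gradient patterns reported for real networks
  (complexity and density rising or falling towards the centre, roughly
  \(D_m\) 1.1→1.2 and 4%→8% coverage) guide the synthetic presets, but
  desk-scale runs make no claim to reproduce measurements that depend on
  the deposited micrographs.
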