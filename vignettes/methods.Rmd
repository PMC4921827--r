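---
title: "Methods: rosette CSC morphometry and stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rosette CSC morphometry and stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscmorph)
```

# Problem

Rosette cellulose synthesis complexes (CSCs) appear in freeze-fracture
transmission electron micrographs as six-lobed particles. Two published
cohort observations anchor this package: the mean area of one imaged lobe
(about 39.5 nm² overall) and the cross-sectional areas of candidate
cellulose synthase (CESA) oligomer models embedded in a membrane. If the
transmembrane footprint of an oligomer of *n* CESAs matches one lobe, the
six-lobed rosette holds 6 × *n* CESAs. `cscmorph` implements both sides
of that comparison — particle metrology on (synthetic or traced) images,
and footprint areas of atomic models — plus the argmin-deviation
stoichiometry call that links them.

The published raw micrographs and refined atomic models are not deposited.
The cohort statistics and the model area table therefore ship as clearly
labelled *published inputs* (`inst/extdata/published_*.tsv`, loaded by
`reference_tables()`); everything else is recomputed from scratch.

# Synthetic micrograph generator (`simulate_micrograph`)

Particles are rendered on a square grid of cells (`cell_size`, default
40 nm) at `pixel_size` (default 0.25 nm/px). Each particle has six (or,
with probability `five_lobe_fraction` = 0.09, five) lobes equally spaced
on a ring of radius `ring_radius` (8.5 nm, so opposite lobes are 17.0 nm
apart), with angular jitter (`angle_jitter_sd` = 2°) and isotropic
centroid jitter (`centroid_jitter_sd` = 0.35 nm). Lobe areas are
Gaussian (`lobe_area_mean` = 39.9 nm², `lobe_area_sd` = 6.5 nm²,
truncated at 5 nm²). A fraction `lobe_shape_mix` (0.5) of lobes are
corner-rounded equilateral triangles with one vertex pointing to the
particle centre; the rest are discs of equal area. The rounded triangle
is the Minkowski sum of an inner equilateral triangle with a disc of
radius 0.1 × side, so its area is available in closed form and the
generator can invert area → side exactly.

Rendering uses a signed-distance soft edge: pixel coverage is
`clamp(0.5 − d/px, 0, 1)` where `d` is the signed distance to the lobe
outline. Lobes are dark (depth 0.35) on a 0.55 background — replica
polarity — with an optional 1 nm bright decoration halo
(`halo_strength` = 0.08) mimicking preferential metal decoration, and
additive Gaussian noise (`noise_sd` = 0.05). Per-particle sub-seeds are
drawn once from the master seed, so output is bit-identical for a fixed
seed and individual particles do not change when `n_particles` changes.

Realism limits: no carbon-film texture, no shadowing direction, no
correlated (replica-grain) noise, no defocus model; lobes never overlap
their neighbours. These are deliberate — the generator's job is
parameter recovery with known ground truth, not photorealism.

`ground_truth_polygons()` converts the per-lobe ground truth to dense
outline polygons (96 vertices), the same representation hand tracing
would produce; their shoelace areas match the true areas to well under
one percent.

# Metrology (`measure_rosette`, `measure_cohort`)

Two perimeter/diameter conventions are computed per particle:

* **Circular**: the smallest enclosing circle of all lobe outline points
  (Welzl-style incremental algorithm; the usual random shuffle is
  omitted because it only affects expected runtime, keeping the function
  deterministic and RNG-silent). `P_circ = 2πr`, `d_circ = P_circ/π`.
* **Hexagonal**: the irregular hexagon through the six outer-centre-edge
  points (the outline point of each lobe farthest along the
  centre-to-centroid direction) gives `P_hex`; the diameter uses the
  regular-hexagon **across-flats** convention `d_hex = (√3/6) P_hex`.
  (The across-corners convention `P/3` would read ~15% larger; the
  across-flats choice reproduces the published circle/hexagon diameter
  offset.)

Lobe areas are absolute shoelace areas of the traced polygons
(self-intersecting polygons are rejected with the offending segment pair
named); opposite-lobe spacings pair lobes (1,4), (2,5), (3,6) after
ordering by polar angle. Particles without exactly six identified lobes
raise a `csc_exclusion` condition and are counted, not measured —
mirroring the exclusion of five-lobed/indistinct particles from six-lobe
metrology.

`summarize_measurements()` reports per-group mean and sample SD (n − 1),
and an **Overall** row that is the unweighted mean of the group means,
not the pooled mean — the convention of the published cohort table
(e.g. the 39.5 nm² overall lobe area is the plain mean of 39.9 and
39.1 nm²).

# Class averaging (`align_stack`, `classify_stable`)

Particles are boxed at 31.6 nm (127 px at the default pixel size; nm
sizes round to the nearest **odd** pixel count so boxes have a centre
pixel), contrast-inverted (`max + min − I`, an involution), and aligned
reference-free. Each sweep realigns every image against the
**leave-one-out** average over a full grid of in-plane rotations
(`angle_step`, default 1°) and integer translations (FFT
cross-correlation peak within ±25% of the box). Excluding the image
being aligned from its own reference removes the self-bias of a plain
evolving average, which we found biases recovered rotations by several
degrees even at infinite SNR. A sweep that would lower the objective
(mean correlation to the full average) is reverted, so the objective is
non-decreasing; iteration stops when the median shift falls below
0.1 px and the median rotation change below one step.

Classification is k-means (Lloyd) on intensity-normalized pixel
vectors, repeated over `n_trials` seeded trials. Initial centres are
chosen **order-invariantly** (images ranked by a seeded random
projection), so class averages do not depend on stack ordering at a
fixed seed. A class is retained only if its membership is reproducible:
the mean best-Jaccard overlap against every other trial must reach
`min_overlap` (0.5); members of unstable classes are left unassigned.
This is an explicit analogue of stable-class averaging as practised in
single-particle 2D classification, not a reimplementation of any
program. Lobe boxes default to 10.3 nm; 10.6 nm is also in circulation
for the same data and both are accepted via the `lobe_box` argument.

# Lobe triangularity (`triangularity`)

A lobe mask (Otsu threshold, largest connected component, holes filled)
is scored `T = max_θ IoU(triangle) − IoU(disc)`, both reference shapes
equal-area and centred on the mask centroid, with the triangle rotation
searched over [0°, 120°). `T > 0` reads "more triangular than round".
Because the visual criterion "triangular" has no unique strictness,
`triangular_fraction()` reports the fraction of lobes above a sweep of
thresholds rather than one number; the published "30–70% triangular"
range corresponds to a band of that curve. Masks touching the box
border are flagged `low_confidence`.

# Footprints (`project_slab`, `union_area`, `build_cn_oligomer`)

Atoms within a closed membrane slab (default half-thickness 2 nm) of an
atomic model project to disks at their (x, y) with their van der Waals
radius (Bondi values; unknown elements fall back to 0.17 nm with a
warning). The union area is measured by rasterization (0.02 nm default
resolution), cross-checked in the tests against a seeded Monte-Carlo
oracle (`union_area_mc`) and closed-form two-disk lens areas.

`blur_and_threshold()` renders the footprint at a finite resolution *R*
(FWHM of a Gaussian): the **hard union indicator** is blurred (so each
disk's contribution integrates to its own area, and the R → 0 limit
recovers the hard footprint exactly), and the isosurface threshold τ is
expressed relative to the peak of an isolated average-area disk under
the same blur. With `tau = "auto"` the threshold is rank-calibrated so
the isosurface area equals the hard union area — operationalizing
"rendered to the edges of the van der Waals model". Note that for dense
multi-disk bundles the auto-calibrated τ can exceed 1: overlapping
neighbours raise the blurred density above the single-disk peak. That
is a property of the calibration, not an error.

`build_cn_oligomer()` packs *n* copies of a monomer footprint at
360°/n spacing, bisecting the ring radius (tolerance 0.01 nm) until the
**adjacent-pair lens-area overlap** does not exceed `contact_tolerance`
× monomer area; the monomer phase is grid-searched for the tightest
packing. The lens-area measure is exact near tangency, where the
bisection converges, and far cheaper than a raster union per candidate;
the *reported* areas always use the raster union. This deterministic
geometric packing deliberately stands in for docking: the downstream
comparison depends only on footprint geometry, not interface
energetics. `build_sixfold_assembly()` places six copies on an 8.5 nm
ring (17.0 nm opposite spacing) and reports — rather than forbids —
inter-lobe clash, since oversized oligomers are expected to clash.

Toy helix-bundle models (`make_toy_bundle`) are clearly labelled
synthetic stand-ins for 7–8-TMH CESA bundles: vertical columns of
pseudo-atoms whose slab projection is one disk per helix.

# Comparison (`stoichiometry_call`, `run_pipeline`)

`stoichiometry_call()` picks the oligomer order with the smallest
|area − mean lobe area| (ties resolve to the smaller, conservative
order) and reports 6 × n as the CESA count. Against the published
oligomer table, both transmembrane models call a trimer per lobe
(41.9 and 44.4 nm² vs 39.5 nm²), i.e. 18 CESAs per rosette.
`published_arithmetic()` recomputes the headline percentages from the
packaged inputs, including both normalization conventions for the
"4–8% larger" negative-stain comparison, whose 8% end uses the larger
denominator.

```{r}
published_arithmetic()[, c("comparison", "percent")]
stoichiometry_call(published_oligomer_areas("8TMH"), 39.5)$cesa_count
```

`run_pipeline()` chains all stages on one seeded configuration and
writes every artifact (TIFF micrograph with a plain-text
`.pixel_size` sidecar, TSVs, class averages, JSON report). Typical
problem sizes: the default 50-particle run renders a ~2900² px
micrograph, measures ~290 lobes, aligns ~45 boxes of 127² px and
finishes in minutes on one CPU; the test suite's 300-particle
parameter-recovery run uses a coarser 0.5 nm/px sampling since
metrology operates on ground-truth polygons.

# Reproducibility

All stochastic steps take explicit integer seeds (default 20160627);
micrographs, alignments, classifications and reports are bit-identical
across runs at a fixed seed. `scripts/acceptance.R --seed <int> --out
<path>` recomputes the headline quantities from scratch against the
installed package and writes them as JSON.
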