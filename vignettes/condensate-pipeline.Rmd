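---
title: "Charge-driven bacterial condensates: the models and methods behind condentag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-driven bacterial condensates: the models and methods behind condentag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condentag)
```

## The scientific problem

Supercationic proteins undergo associative phase separation (complex
coacervation) with cellular RNA in *E. coli*, condensing into bright
intracellular foci. Rather than re-engineering a protein's whole surface,
a short C-terminal cationic tag — repeats of the 9-mer `GGSKKRKKR`, +6 per
repeat — can push a globular domain across the phase boundary. Two
questions drive the analysis this package implements:

1. **Design**: given a globular domain, how many tag repeats (and linker
   lysines) put the fusion at a chosen net charge — +6 for condensates
   that form and later disassemble during growth ("transient"), or at or
   above +12 for condensates that persist?
2. **Readout**: given fluorescence micrographs of cells, what fraction of
   cells contain condensates, how enriched is the protein in the
   condensed phase, and does a strain's occupancy over hours
   post-induction classify it as none / transient / persistent?

## The charge model

Net charge is the integer sum of side-chain charges at neutral pH:
K/R = +1, D/E = −1, everything else 0. Histidine is treated as neutral,
termini are ignored, and no chromophore correction is applied. This
convention reproduces the canonical labels of the engineered GFP panel —
sfGFP computes to −7 (`read_fasta()` on the bundled `sfGFP.fasta`), and
it makes a 6xHis purification tag charge-neutral, so stated charges are
unaffected by its presence. Non-canonical letters (X, B, Z, U) are
rejected by default; a permissive mode maps them to charge 0 with a
warning, which matters only for proteome-scale FASTA input.

`design_tag()` solves the design question exactly. Every integer charge
at or above the domain charge is reachable with `n` repeats (+6 each)
plus 0–5 linker lysines (+1 each, placed between the domain C-terminus
and the first repeat, as in the sfGFP constructs, where a single linker
lysine makes the −7 domain charge-equivalent with the others). Transient
mode lands exactly on +6 and is infeasible for domains above +6 (tags
only add positive charge); persistent mode lands on the smallest
achievable value at or above the target. The default persistent target is
+12 — the charge at and above which condensate formation was uniformly
observed — rather than the weaker "just above +6"; both are exposed as
arguments because the gap between +7 and +11 is empirically ambiguous
territory near the phase boundary.

## The imaging pipeline

The analysis chain mirrors a MicrobeJ + custom-script workflow:

1. **Rolling-ball background subtraction** (`rolling_ball_subtract()`,
   default radius 100 px): the background is the grayscale opening of the
   image with a ball-shaped structuring element — the surface traced by a
   ball of the given radius rolling under the intensity landscape —
   treating intensity and pixel units as commensurate (the classical
   convention; a paraboloid element is available as an option). Borders
   are replicate-extended. For radii above 16 px the image is first
   shrunk by block-minimum (factor 2/4/8 by radius), the ball is rolled
   at reduced radius, and the background is bilinearly re-expanded and
   clipped under the image — the classical speed-up; small radii use the
   exact full-resolution opening, which is what the oracle-equivalence
   tests compare against a brute-force double loop.
2. **Li thresholding** (`li_threshold()`): the minimum-cross-entropy
   threshold via the iterative fixed point started from the image mean.
   Intensities are shifted to strictly positive values (one-millionth of
   the range) so partition means admit logarithms. On images whose
   histogram has an empty gap between modes the cross-entropy objective
   is flat across the gap; any point of the plateau is a valid minimiser
   and the tests therefore compare decision boundaries in objective
   terms rather than raw threshold values.
3. **Segmentation** (`segment_cells()`): binarise, fill holes, label
   8-connected components, discard components touching the image border,
   and filter on shape. Coordinates are 0-based (row, col) in the medial
   axis; masks use 8-connectivity.
4. **Condensate calling** (`detect_condensates()`): within each cell,
   pixels at least `threshold` (default 1.20, i.e. 20% brighter) times
   the cytoplasm reference form candidate foci; 8-connected foci smaller
   than `min_focus_px` (default 4 px, a guard against single-pixel noise
   that the source workflow leaves unspecified) are dropped. The
   cytoplasm reference is the median intensity in a 3 px-radius disk at
   the midpoint of the medial axis — the median rather than the mean so
   a stray bright pixel (or a condensate edge encroaching on the
   midpoint) cannot inflate the reference; the mean is available as an
   option. Calling is ratio-based, hence invariant to global intensity
   scaling.
5. **Strain statistics**: `fraction_with_condensates()` counts
   condensate-containing cells; `classify_strain()` applies the 0.11
   cell-fraction cutoff (boundary inclusive: the negative side is stated
   as "below 0.11", so a fraction of exactly 0.11 classifies as
   forming); `threshold_sweep()` re-calls at thresholds 1.05–2.00
   (default step 0.05; endpoints are prescribed, the grid is ours).
   Because super-threshold pixel sets are nested, sweep fractions are
   provably non-increasing.
6. **Time courses**: fractions are computed per biological replicate and
   then summarised as mean ± sample SD (n − 1; with three replicates the
   denominator matters). `persistence_class()` uses the replicate mean:
   persistent if the final (largest) timepoint is at or above the
   cutoff, transient if an earlier timepoint reached it but the final
   one did not, none otherwise. "Fully disassembled" is thus
   operationalised as "below the cutoff at the final timepoint" — an
   explicit stand-in for a visual judgement. `expression_proxy()`
   computes blank-corrected fluorescence/OD as the intracellular
   concentration proxy, masking non-positive ODs.

### Medial axes and shape descriptors

Cells are measured on their medial axis: the mask is thinned with the
Guo–Hall two-subiteration algorithm and the axis is the
Euclidean-weighted diameter path of the skeleton (Dijkstra twice). We
use Guo–Hall rather than the more common Zhang–Suen because the latter
over-erodes thick shapes oriented near 45°, occasionally collapsing a
whole cell's skeleton; as a second line of defence, a skeleton whose
implied length falls below its width triggers a principal-component
fallback (per-bin mean perpendicular position along the principal axis),
which is exact for straight rods.

Descriptors:

* **length** — geodesic length of the smoothed axis (a 5-point moving
  average removes the zigzag of the discrete skeleton, which otherwise
  inflates length by a few percent), plus a ray extension from each end
  along the local axis direction to the mask boundary. The extension
  recovers the pole caps and any over-erosion by thinning; on rendered
  spherocylinders it is accurate to about ±1 px.
* **width** — twice the mean Euclidean distance transform over the
  central half of the axis (the caps taper and would bias a full-axis
  mean); accurate to about ±0.5 px.
* **circularity** — 4πA/P² with the perimeter measured as the Freeman
  8-chain length of the ordered contour (diagonal steps √2). A naive
  boundary-pixel count underestimates P and pushes digitised rods above
  1.0, defeating the filter.
* **angularity** — the mean absolute turning angle (radians) along the
  smoothed axis resampled every 3 px; near 0 for straight rods. This is
  a documented approximation: the constraint it stands in for is not
  specified beyond its name in the source workflow.

Default shape constraints (area 150–2500 px², length 1.0–6.0 µm, width
0.5–1.6 µm, circularity 0.2–0.9, angularity ≤ 0.35 rad) are stand-ins
chosen for rod-shaped bacteria at 0.065 µm/px; the exact production
values were never published and all are exposed in
`shape_constraints()`. A digitised disk has chain-perimeter circularity
≈ 0.91, so round debris falls above the 0.9 ceiling while even stubby
2 × 1.1 µm capsules (true circularity ≈ 0.88) are kept.

## The synthetic scene generator

`generate_scene()` renders fields of spherocylindrical cells with known
ground truth so every stage can be benchmarked without real data. Cells
are placed on a jittered grid of disjoint slots (overlap is impossible
by construction; oversubscription errors out with guidance), with
uniform cytoplasm on a uniform background. Condensate-bearing cells
(Bernoulli with `condensate_fraction`) receive disk foci on the medial
axis — at a pole by default, the typical appearance in micrographs,
which also keeps the midpoint reference clean; uniform-along-axis
placement is available to stress-test the reference. Focus pixels are
brightened to `partition_ratio` (ρ) times the cytoplasm. The field is
blurred with a Gaussian PSF and corrupted with Poisson shot noise plus
Gaussian read noise, then clipped to the bit depth.

Rendering is binary-membership (a pixel belongs to a shape iff its
centre does), so blur- and noise-free scenes obey exact arithmetic: the
interior reads exactly the cytoplasm intensity, the focus/interior
ratio is exactly ρ, and total intensity is exactly
background·area + Σ cytoplasm·cell_area + Σ (ρ−1)·cytoplasm·focus_area.
These identities anchor the unit tests.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.065 µm/px | 100×/1.4 NA widefield |
| cell length, width | 2–4 µm, 0.9–1.1 µm | typical *E. coli* rods |
| PSF sigma | 1.2 px | ≈ 0.21 λ/NA at λ = 510 nm, 65 nm pixels |
| cytoplasm / background | 120 / 10 a.u. | moderate-SNR expression imaging |
| noise | Poisson (gain 1) + Gaussian read sd 2 | shot-noise-limited camera; magnitudes keep the false-positive cell fraction at threshold 1.20 well below the 0.11 cutoff |
| ρ | 1.6 | mid-range partitioning between the weakest observed enrichment (~1.5-fold) and strongly supercharged variants |
| condensate fraction | 0.8 | a clearly condensate-forming strain |
| focus radius | 0.25–0.35 µm, 1 per cell | plausible placeholders: condensate size and number per cell are not reported |

What the generator does *not* emulate: physically realistic coacervation
(no nucleation/growth dynamics, no intensity gradient within foci), 3D
sectioning, cell crowding/overlap, debris and uneven illumination
beyond what the rolling ball removes, and cell division between
timepoints. Passing tests therefore demonstrate that the *computational
chain* recovers known ground truth under realistic optics and noise —
not that the thresholds would be optimal on any particular real
dataset.

`generate_growth_table()` supplies the expression side: OD follows a
logistic curve; fluorescence accumulates as
dF/dt = rate · OD(t) · exp(−t/τ) with an expression-shutdown constant
τ = 5 h, so the fluorescence/OD proxy rises over the first hours and
plateaus near 12 h, the observed phenomenology. With shutdown disabled
and constant OD the proxy is exactly rate · t, which the tests assert.

## Numerical choices and degenerate inputs

* Every stochastic step is seeded; `derive_seed()` fans a single global
  seed out to per-(variant, replicate, timepoint) scene seeds below
  2³¹, so any stage can be re-run in isolation, and `run_pipeline()` is
  bit-reproducible (outputs carry an MD5 hash of the canonical-JSON
  config).
* Blank images segment to an empty cell list (not an error); constant
  images are a degenerate-image error for `li_threshold()`; a medial
  axis shorter than 3 points or an empty midpoint disk is a
  degenerate-cell error; empty call lists are an empty-input error.
* `fraction_in_window(lo, hi)` uses inclusive bounds; the empirical CDF
  is a right-continuous step function over observed charges.
* Enrichment is reported as NA (not 1) when no focus survives, so
  strain-level enrichment summaries average over detected condensates
  only.

## Problem sizes in the test-suite

The suite benchmarks parameter recovery on 20 seeded scenes of 200
cells at ρ = 1.6 under default optics and noise (plus ρ = 1 scenes for
the false-positive regime and a 500-cell scene for the occupancy
statistic), and recovers transient/persistent phenomenology from
four-timepoint synthetic courses of 40-cell scenes. These sizes give
binomial standard errors of a few percent on per-scene fractions while
keeping the whole suite in the low minutes on one CPU.

## Known limitations

* The charge model is a neutral-pH integer approximation: no pKa
  shifts, no isoelectric points, no structural electrostatics. It is
  the convention under which the design rules (+6 transient, ≥ +12
  persistent) were formulated, and those rules are empirical
  observations for GFP-family domains in *E. coli* — not guaranteed to
  transfer to arbitrary proteins or hosts.
* A condensate overlapping the cell midpoint would inflate the
  cytoplasm reference and suppress the call; the median mitigates but
  does not resolve this, and polar placement in the generator means the
  synthetic benchmarks exercise it only via the uniform-placement
  option.
* Segmentation assumes non-touching rods; confluent fields would need
  watershed splitting, which is out of scope.
* The enrichment ratio is computed per cell from surviving focus pixels
  and is threshold-dependent near ρ ≈ threshold; it recovers the true
  partition ratio within ~10% at ρ = 1.6 under default blur and noise,
  with a small downward bias from PSF smearing of focus edges.
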