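# condentag

Charge-based engineering of intracellular biomolecular condensates in
bacteria, and their quantification in fluorescence micrographs.

Supercationic proteins phase-separate with cellular RNA in *E. coli*
(complex coacervation), forming membraneless condensates visible as
bright foci. Appending a short cationic peptide tag — repeats of the
9-mer `GGSKKRKKR`, each contributing +6 — supercharges a protein of
interest without re-engineering its surface. Overall net charge governs
whether condensates form: fusions at **+6** sit at the phase boundary
and form *transient* condensates that disassemble as expression rises
through growth, while fusions at **≥ +12** form *persistent*
condensates. `condentag` implements both sides of this workflow:

* **Charge module** — integer net charge at neutral pH
  (K/R = +1, D/E = −1, H neutral, termini ignored), per-residue charge
  profiles, proteome-wide charge distributions with window fractions,
  and a tag designer that picks the smallest `[GGSKKRKKR]n` tag (plus
  0–5 linker lysines) to land a fusion exactly on +6 (transient) or on
  the smallest achievable charge ≥ +12 (persistent).
* **Imaging module** — the MicrobeJ-style readout chain: rolling-ball
  background subtraction (100 px ball, grayscale opening), Li
  minimum-cross-entropy thresholding, shape-constrained segmentation of
  rod-shaped cells with medial axes, per-cell condensate calls (pixels
  ≥ 1.20× the cytoplasm reference at the cell midpoint, 8-connected
  foci of ≥ 4 px), the fraction-of-condensate-containing-cells
  statistic with its 0.11 strain cutoff, intensity-ratio sweeps over
  1.05–2.00, and time-course classification (none / transient /
  persistent) plus the fluorescence/OD expression proxy.
* **Synthetic data** — a seeded generator of spherocylindrical-cell
  micrographs with full ground truth (per-cell masks, condensate
  presence, partition ratio ρ), plus logistic growth/expression tables,
  so the entire pipeline is testable without any external data.

## Worked example

Design tags for two globular domains, then run the bundled end-to-end
demonstration (simulate → subtract background → segment → call →
classify):

```r
library(condentag)

net_charge("GGSKKRKKR")
#> [1] 6

design_tag(-7, "transient")    # sfGFP-like domain
#> <tag_design> domain(-7) (-7) + 1x K + [GGSKKRKKR]2 -> predicted +6 (transient)

design_tag(+6, "persistent")
#> <tag_design> domain(+6) (+6) + 0x K + [GGSKKRKKR]1 -> predicted +12 (persistent)

res <- run_pipeline(demo_config(seed = 1))
res$fractions[, c("variant", "timepoint", "n_cells", "n_with", "fraction")]
#>    variant timepoint n_cells n_with  fraction
#> 1 GFP-tag3         6      12      8 0.6666667
#> 2 GFP-tag3        24      12     11 0.9166667
#> 3      GFP         6      12      0 0.0000000
#> 4      GFP        24      12      0 0.0000000

res$classification[, c("variant", "net_charge", "final_fraction", "class")]
#>    variant net_charge final_fraction      class
#> 1      GFP          0      0.0000000       none
#> 2 GFP-tag3         18      0.9166667 persistent
```

The `-7` domain needs two tag repeats plus one linker lysine to reach
+6 (−7 + 1 + 2·6); the +6 domain needs a single repeat to reach +12.
In the demo pipeline the tagged strain (ρ = 1.8, most cells carrying a
condensate) is called condensate-forming — 11 of 12 segmented cells
show foci at least 20% brighter than their midpoint cytoplasm at 24 h —
while the untagged control stays at fraction 0, below the 0.11 cutoff.

A thin CLI over the same functions lives at
`inst/scripts/condentag.R` (subcommands `simulate`, `segment`, `call`,
`charge`, `design-tag`, `proteome-cdf`, `run`).

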