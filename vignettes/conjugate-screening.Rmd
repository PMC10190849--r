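---
title: "Conformational screening of modular peptide-drug conjugates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational screening of modular peptide-drug conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

Enzymatically activated peptide-drug conjugates circulate as soluble
monomers and assemble into fibrils only after a protease (here
caspase-3/7, cleaving C-terminal to the aspartate of a DEVD substrate)
releases the segment that keeps the amyloid-derived assembly motif
KLVFFAE covered. A candidate conjugate is a single chain partitioned into
modules:

* `R1` — targeting and tailoring segment (an XIAP-binding heptapeptide or
  a mutated control, followed by the DEVD substrate),
* `R2`, `R4` — optional extensions flanking the assembly motif, used to
  graft dyes (Cy, FITC) or extra residues,
* `ASM` — the conserved assembly module KLVFFAE,
* `R3` — the drug site on the side-chain amine of the assembly module's
  lysine.

Whether a design stays dispersed before activation is governed by how much
of the assembly module's surface the other modules bury, and by the
network of non-covalent contacts holding that cover in place. `pepconj`
implements the computational side of this screen: solvent exposure of the
assembly module (%SASA) with a dispersity threshold, module-pair
interaction landscapes, the exposure change on cleavage, and critical
aggregation concentrations (CAC) from Thioflavin T (ThT) titrations.

## The %SASA statistic

For a conformational ensemble bound to a topology, each frame contributes

\[
\%\mathrm{SASA} = 100 \cdot
\frac{\mathrm{SASA}(\text{ASM atoms in full-molecule context})}
     {\mathrm{SASA}(\text{ASM atoms alone, same coordinates})},
\]

and the reported statistic is the mean of per-frame percents (the
percent-of-means aggregate is also exported; the two differ only when
frame-to-frame exposure varies strongly). The literature this package
follows never defines the normalisation of its exposure percentage; the
isolated-module baseline at identical coordinates was chosen because it
makes the statistic a true fraction in [0, 100] by the occluder-removal
argument below, and it is stamped into every report
(`denominator_mode`). A consequence worth remembering when comparing
against other software: a published threshold may not transfer across
normalisations.

Classification uses a strict inequality: values above the threshold
(default 75) are `assembly_prone`, values at or below it `dispersed`, so
exactly 75.0 classifies as dispersed.

SASA itself is Shrake-Rupley: each atom's van der Waals sphere is
expanded by the probe radius (default 1.4 Å, water), sampled with a
deterministic generalized-spiral lattice (default 960 points; the
discretisation error falls roughly as 1/n), and a sample point is buried
if it lies inside (or exactly on) any neighbouring expanded sphere. Two
numerical conventions follow from the boundary rule: coincident atoms of
equal radius occlude each other completely, and because the lattice is
fixed in space, a rigid rotation of the molecule changes areas by a small
discretisation term (about 0.5% of the total at 480 points). There is no
Monte-Carlo noise anywhere: identical inputs give bit-identical areas.

## Cleavage and the exposure delta

`cleave()` cuts after the last residue of every DEVD occurrence (the
canonical caspase P1 aspartate); ligands travel with their anchor
residue, and module spans are re-indexed per product.
`hydrolysis_exposure_delta()` recomputes %SASA of the product that
retains the assembly module *on the same coordinates* with the released
atoms deleted — a frozen-geometry simplification (no relaxation of the
product; the study this mirrors relaxed products by molecular dynamics,
which is out of scope here). Deleting occluders can never bury a sphere
point that was accessible, so the delta is non-negative for every input,
with equality exactly when no removed atom lies within occlusion range
(r_i + r_j + 2 · probe) of any module atom. This theorem is
property-tested, and it is the reason the statistic is bounded in
[0, 100].

## Interaction landscapes

Three detectors run per frame, all on heavy atoms (the generators omit
hydrogens; detection is therefore distance-only and every report records
that):

* hydrogen bond — donor/acceptor heavy-atom distance ≤ 3.5 Å, one record
  per (donor residue, acceptor residue, donor atom, acceptor atom);
* salt bridge — minimum distance between a cationic group (Lys/Arg side
  chain, free N-terminus) and an anionic group (Asp/Glu side chain, free
  C-terminus, ligand sulfonate/carboxylate) ≤ 4.0 Å, one record per group
  pair;
* hydrophobic contact — apolar atoms (C/S not bonded to N/O, plus apolar
  ligand atoms) within 5.0 Å; the reported quantity is the number of
  distinct participating atoms, not pairs.

Hydrogen-bond and hydrophobic pairs require a sequence separation of at
least 2 so that covalent neighbours do not register; salt bridges are
exempt (adjacent Lys/Asp side chains form genuine bridges). None of these
cutoffs is anchored in the source study, which states no geometric
definitions — they are common conventions, configurable through
`interaction_criteria()` and recorded in outputs. Landscapes aggregate
per module pair (self-pairs included): mean counts per frame,
inter-/intra-module totals, and per-contact occupancy (fraction of frames
present), with `lifetime_series()` exposing single-contact presence
vectors.

## CAC from ThT titrations

ThT fluorescence rises steeply once lamellar β-sheet assemblies form, so
a dose-response curve bends upward at the critical aggregation
concentration. `fit_cac()` models fluorescence as a continuous
two-segment linear function of log2 concentration,

\[ y = a + b_1 (\ell - c) + (b_2 - b_1)\max(\ell - c, 0), \qquad
   \ell = \log_2 x, \]

minimising least squares over a deterministic breakpoint grid: the
interior dose points plus `grid_points` equal subdivisions of each
interior dose interval. Because refined grids nest, refinement can only
lower the RSS, and a breakpoint that lands on a dose point is reported as
that dose exactly. An aggregation call is valid only if the
post-breakpoint slope exceeds the pre-breakpoint slope *and* the
two-segment model beats a single line in an F test (α = 0.05, two extra
parameters); otherwise the estimate is censored and rendered
`>= <max dose> uM`, the same way soluble designs are reported in the
assay literature. The fit returns a classed model object with the usual
`print`/`summary`/`coef`/`predict`/`fitted`/`residuals`/`plot` methods
and an optional bootstrap confidence interval.

The synthetic generator mirrors this model: a shallow background slope
(default 5 fluorescence units per concentration doubling), a steep
post-breakpoint slope (default 300), baseline 100 at the lowest dose and
multiplicative Gaussian noise. The default dose grid is eight two-fold
dilutions from 3.125 to 400 μM — wide enough to resolve the lowest
reported breakpoint (12.5 μM) with at least two pre-breakpoint doses
while keeping the published 400 μM ceiling that defines censoring.
Soluble designs are emulated with a breakpoint far above the ceiling
(1600 μM), which the fit correctly censors.

## What the synthetic conformations are — and are not

MD trajectories for these conjugates are not publicly available, so the
generators produce what the analysis needs and nothing more:

* `build_conformation()` — ideal-geometry backbones (natural-extension
  construction with Engh-Huber-style bond lengths/angles) in helix
  (φ, ψ = −60°, −45°), extended (−135°, 135°) or hairpin motifs
  (strands at −139°, 135° around a two-residue type-I′ turn), side
  chains at extended default rotamers, coarse planar ligand templates
  grafted at their anchors. Everything is deterministic.
* `plant_contacts()` — relocates designated atoms so that requested
  contacts satisfy their detector criteria by a stated margin, choosing
  among deterministic candidate directions the position farthest from
  all other atoms, then re-detects and *fails loudly* if a planted
  contact is missing or an unplanned same-kind contact appeared between
  the named partners.
* `perturb_ensemble()` — i.i.d. Gaussian displacements per atom and
  frame around the input structure (frame 1 is the input; the mean
  all-atom RMSD of perturbed frames approaches amplitude · √3).
* `generate_titration()` — the two-segment dose-response above.

These emulate the *inputs* of the analysis, not the physics: there is no
force field, no Boltzmann weighting, no correlated motion, no solvent.
Passing tests therefore demonstrate that the estimators and detectors
recover exactly what was planted under known conditions — they say
nothing about how a particular real conjugate behaves in water. Planted
fixtures use the extended motif because it has a verified-clean contact
background; the default side-chain rotamers were chosen once so that an
extended chain carries no accidental contacts, and the worked-example
fixtures plant salt-bridge-only pairs at 3.8 Å (inside the 4.0 Å
salt-bridge cutoff, outside the 3.5 Å hydrogen-bond cutoff) precisely so
that the two detectors' outputs can be compared to the published lists
independently; pairs listed under both interaction kinds are planted at
2.9 Å.

## Registry provenance

The built-in design registry is a reconstruction: the source study
printed module descriptions, not full sequences. The Pbeta platform is
encoded as AVPIAQK + DEVD + KLVFFAE, which is consistent with every
residue label in its published interaction analysis (PHE16, VAL14, ALA5,
LYS7, LYS12, ASP11, GLU9 and, for the Cy variant, ALA1, VAL2, ILE4,
GLN6, PHE15, ALA17); Palpha substitutes MDEKAQK and keeps DEVD, which is
required for the published observation that both R4C variants cleave to
the same product. Two placements are undocumented and therefore package
choices flagged in the registry's provenance notes: FITC is anchored at
the C-terminus of the assembly module's final glutamate, and the pyrene
demo drug sits on the assembly-module lysine side chain (the declared R3
drug site). Conjugation consumes the anchor's free amine/thiol
chemistry, so an anchored lysine loses its cationic group. All records
are plain YAML and can be overridden with user files.

## Problem sizes and tolerances used by the shipped tests

The test suite runs the geometry oracles at 240-480 lattice points, the
detector-equivalence check on 50 random conformations of up to 200
atoms, the occluder-removal theorem on 100 single-frame fixtures at 120
points, CAC recovery over 20 seeded replicates at 5% noise (median error
under 20%), and the eight-design determinism screen at 4 frames and 120
points — sizes chosen so the whole suite completes in about a minute on
one core while still exercising every code path at the documented
tolerances. Production runs default to 960 lattice points and 20 frames;
all such knobs live in `sasa_options()`, `interaction_criteria()` and
`run_config()`.

## Known limitations

* Frozen-geometry cleavage underestimates the exposure gain of a product
  that would relax and extend in solution.
* Distance-only hydrogen-bond detection cannot distinguish donors from
  acceptors sterically blocked by geometry that explicit hydrogens would
  reveal.
* The secondary-structure rule is a Ramachandran rectangle classifier
  (helix: φ ∈ [−100, −30], ψ ∈ [−80, −5]; strand: φ ∈ [−180, −45],
  ψ ∈ [90, 180]; termini are coil); it is hydrogen-free by design and
  not a DSSP replacement.
* Ligand templates are coarse planar blobs with correct chemistry flags;
  do not use them for anything geometric beyond contact counting.
* Published simulation-derived magnitudes (trajectory RMSDs, exact %SASA
  values, mean contact counts) depend on unreported trajectories and
  force fields and are deliberately not reproduction targets; the
  package reproduces the *procedures* and their decision rules.

## A minimal session

```{r example}
library(pepconj)

cfg <- run_config(designs = c("Pbeta", "Pbeta_R2C", "Pbeta_R4C"),
                  n_frames = 10, seed = 1,
                  sasa = sasa_options(n_points = 480))
screen <- run_design_screen(cfg)
screen[, c("design", "percent_sasa", "classification", "cleavage_delta")]

tht <- generate_titration(25, noise_cv = 0.05, seed = 1)
fit <- fit_cac(tht)
summary(fit)
plot(fit)
```
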