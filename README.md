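# pepconj

Conformational screening of modular, enzymatically activated
self-assembling peptide–drug conjugates.

## The problem

A caspase-activated peptide–drug conjugate must stay dispersed in
circulation and assemble into fibrils only after cleavage. The designs
this package screens are single chains built around the amyloid-derived
assembly motif **KLVFFAE** (`ASM`), flanked by a targeting/tailoring
segment ending in the caspase-3/7 substrate **DEVD** (`R1`), optional
extensions (`R2`, `R4`) carrying dyes such as Cy or FITC, and a drug site
on the assembly-module lysine side chain (`R3`). Whether a candidate
disperses or aggregates before activation is decided by how much of the
assembly module's surface the other modules bury and by the non-covalent
contacts that hold the cover in place.

`pepconj` is aimed at people designing such conjugates (or re-analysing
conformational ensembles of them): it quantifies the cover, the contacts
and the activation switch, and calibrates the accompanying aggregation
assay.

## What it computes

* **%SASA of the assembly module** — per frame,
  `100 · SASA(ASM atoms in context) / SASA(ASM atoms alone, same
  coordinates)`, averaged over the ensemble. SASA is Shrake–Rupley with a
  deterministic spiral lattice (no Monte-Carlo noise; probe 1.4 Å, 960
  points by default). The 75% rule classifies designs: `%SASA > 75` →
  `assembly_prone`, otherwise `dispersed`.
* **Cleavage exposure delta** — %SASA recomputed on the same coordinates
  with the released segment deleted (frozen geometry). Provably ≥ 0:
  removing occluders can only expose the module.
* **Interaction landscapes** — hydrogen bonds (donor–acceptor ≤ 3.5 Å),
  salt bridges (opposite formal charge groups, minimum distance ≤ 4.0 Å)
  and hydrophobic contacts (apolar atoms ≤ 5.0 Å), aggregated per module
  pair with per-contact occupancies and lifetimes.
* **CAC from ThT titrations** — two-segment least squares on log2
  concentration, `y = a + b₁(ℓ − c) + (b₂ − b₁)·max(ℓ − c, 0)`, breakpoint
  `2^c` searched on a nested dose-interval grid; censored as
  `">= 400 uM"` when the slope increase is not significant.
* **Stability metrics** — Kabsch-superposed RMSD series, radius of
  gyration, Ramachandran-rule secondary structure.
* **Synthetic inputs** — ideal-geometry helix/hairpin/extended
  conformations with planted contacts, Gaussian-perturbed ensembles and
  synthetic titrations, standing in for unavailable MD trajectories and
  assay data. Multi-model PDB and CSV round trips make every stage
  consumable from files.

## Worked example

```r
library(pepconj)

get_design("Pbeta_R4C")
#> <conjugate_topology> Pbeta_R4C
#>   sequence: AVPIAQKDEVDKLVFFAECG (20 residues)
#>   R1  residues 1-11
#>   ASM residues 12-18
#>   R4  residues 19-20, ligands: Cy
#>   cleavage motif: DEVD

cfg <- run_config(designs = c("Pbeta", "Pbeta_R2C", "Pbeta_R4C"),
                  n_frames = 10, seed = 1,
                  sasa = sasa_options(n_points = 480))
run_design_screen(cfg)[, c("design", "percent_sasa", "classification",
                           "product_percent_sasa", "cleavage_delta")]
#>      design percent_sasa classification product_percent_sasa cleavage_delta
#> 1 Pbeta_R4C         71.9      dispersed                 95.5          23.58
#> 2     Pbeta         79.2 assembly_prone                100.0          20.82
#> 3 Pbeta_R2C         82.0 assembly_prone                 85.0           3.06
```

Read: on synthetic hairpin ensembles, the C-terminal Cy modification
(`Pbeta_R4C`) buries enough of KLVFFAE to classify as dispersed and gains
23.6 percentage points of exposure on cleavage — the activation switch —
while the unmodified platform and the R2-modified variant stay
assembly-prone, and the R2 variant barely responds to cleavage because
its dye does not sit on the released segment.

```r
run_cac_table(run_config(seed = 1))[, c("molecule", "cac_label")]
#>      molecule cac_label
#> 1      Palpha   12.5 uM
#> 2       Pbeta  26.79 uM
#> 3  Palpha_R4C >= 400 uM
#> 4   Pbeta_R4C >= 400 uM
#> 5   Pbeta_R2C    200 uM
#> 6   Pbeta_R4F >= 400 uM
#> 7   Pbeta_R4P >= 400 uM
#> 8 Pbeta_R4C_D >= 400 uM

summary(fit_cac(generate_titration(25, noise_cv = 0.05, seed = 1)))
#> Two-segment breakpoint regression on log2 concentration
#>   doses: 8 (3.125-400 uM)
#> CAC: 26.79 uM
#>   slopes (per doubling): pre = 7.185, post = 316.5
#>   RSS = 1710, slope-increase F-test p = 4.75e-05
```

The aggregating designs recover their planted breakpoints (12.5, 25 and
200 μM, within noise); designs whose breakpoint lies above the tested
range censor at the 400 μM ceiling, rendered exactly as assay tables
print them.

A thin command-line wrapper with `screen`, `cac`, `cleave`, `landscape`
and `synth` subcommands lives at `inst/scripts/pepconj-cli.R`. The
methods vignette (`vignettes/conjugate-screening.Rmd`) documents the
model, conventions, default parameters and limitations.

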