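# Built-in conjugate design registry.
# The source design study printed module descriptions but not full sequences;
# every record below is a synthetic reconstruction from those descriptions
# and the residue labels of the interaction analysis (provenance field).
# Module layout (N to C): R1 targeting+tailoring (XIAP-binding or mutated
# control heptapeptide followed by the caspase-3/7 DEVD substrate), optional
# R2 insertion, ASM assembly module (KLVFFAE, invariant), optional R4
# extension; R3 is the drug site on the side-chain amine of the assembly
# module's lysine.
cleavage:
  motif: DEVD
designs:
  - name: Palpha
    motif: helix
    provenance: >
      Synthetic reconstruction; control targeting module MDEKAQK (AVPI
      mutated to MDEK) + DEVD + KLVFFAE; alpha-helical backbone design.
    modules:
      - {id: R1, sequence: MDEKAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
    ligands: []
  - name: Pbeta
    motif: hairpin
    provenance: >
      Synthetic reconstruction; XIAP-targeting AVPIAQK + DEVD + KLVFFAE;
      beta-hairpin backbone design. Residue numbering validated against the
      interaction-analysis labels (PHE16, VAL14, ALA5, LYS7, LYS12, ASP11,
      GLU9).
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
    ligands: []
  - name: Palpha_R4C
    motif: helix
    provenance: >
      Palpha with CG appended in the R4 domain and Cy grafted on the added
      cysteine side chain.
    modules:
      - {id: R1, sequence: MDEKAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
      - {id: R4, sequence: CG}
    ligands:
      - {template: CYD, module: R4, anchor_module: R4, anchor_position: 1, site: side_chain}
  - name: Pbeta_R4C
    motif: hairpin
    provenance: >
      Pbeta with CG appended in the R4 domain and Cy grafted on the added
      cysteine side chain.
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
      - {id: R4, sequence: CG}
    ligands:
      - {template: CYD, module: R4, anchor_module: R4, anchor_position: 1, site: side_chain}
  - name: Pbeta_R2C
    motif: hairpin
    provenance: >
      Pbeta with GC inserted in the R2 domain (between the DEVD substrate
      and the assembly module) and Cy grafted on the inserted cysteine.
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: R2, sequence: GC}
      - {id: ASM, sequence: KLVFFAE}
    ligands:
      - {template: CYD, module: R2, anchor_module: R2, anchor_position: 2, site: side_chain}
  - name: Pbeta_R4F
    motif: hairpin
    provenance: >
      Pbeta with FITC in the R4 domain; the attachment residue is not
      described in the source study, so FITC is anchored at the C-terminus
      of the assembly module's final glutamate (reconstruction).
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
      - {id: R4, sequence: ''}
    ligands:
      - {template: FIT, module: R4, anchor_module: ASM, anchor_position: 7, site: C_term}
  - name: Pbeta_R4P
    motif: hairpin
    provenance: >
      Pbeta with the short peptide PDIFD appended in the R4 domain.
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
      - {id: R4, sequence: PDIFD}
    ligands: []
  - name: Pbeta_R4C_D
    motif: hairpin
    provenance: >
      Pbeta_R4C loaded with the model drug pyrene on the side-chain amine of
      the assembly module's lysine (the R3 drug site).
    modules:
      - {id: R1, sequence: AVPIAQKDEVD}
      - {id: ASM, sequence: KLVFFAE}
      - {id: R4, sequence: CG}
    ligands:
      - {template: CYD, module: R4, anchor_module: R4, anchor_position: 1, site: side_chain}
      - {template: PYR, module: R3, anchor_module: ASM, anchor_position: 1, site: side_chain}
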