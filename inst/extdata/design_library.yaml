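# Four-region design library for the abemaciclib-analogue scaffold.
#
# The scaffold template carries one {R1}..{R4} token per modification region:
#   R1  benzimidazole-type ring system on the pyrimidine (hinge-distal pocket)
#   R2  substituent at the pyrimidine 5-position (hydrophobic cavity)
#   R3  substituent on the aminopyridine ring (P-loop contact)
#   R4  substituent on the distal piperazine nitrogen (solvent-exposed)
# Fragment SMILES are spliced at the token; "" means hydrogen. Fragments use
# ring-closure digits >= 4 to stay clear of the scaffold's own rings.
#
# one_region entries labelled R1a, R1b, R1f, R1i, R1m, R2a, R2b, R2e, R2f,
# R2h, R3e, R3f, R3i, R4a, R4b, R4g, R4i, R4j follow the published library;
# the remaining entries are SYNTHETIC placeholders (plausible small groups)
# filling the undisclosed slots of the 42-member library.
scaffold:
  template: "N1(CCN({R4})CC1)Cc1ccc(Nc2ncc({R2})c({R1})n2)nc1{R3}"
  description: >
    Amine-pyrimidine hinge binder: 2-anilinopyrimidine core hydrogen-bonding
    to the kinase hinge, aminopyridine arm carrying a methylene-linked
    piperazine.
  base:
    R1: "c4nc5cc(F)ccc5n4C(C)C"
    R2: "F"
    R3: ""
    R4: "CC"
one_region:
  R1:
    - {label: R1a, smiles: "c4ccccn4", description: "pyridin-2-yl"}
    - {label: R1b, smiles: "c4cn(C(C)C)nn4", description: "1-isopropyl-1H-1,2,3-triazolyl"}
    - {label: R1c, smiles: "c4nccn4C", description: "1-methylimidazol-2-yl"}
    - {label: R1d, smiles: "c4ccccc4", description: "phenyl"}
    - {label: R1e, smiles: "c4ccc(F)cc4", description: "4-fluorophenyl"}
    - {label: R1f, smiles: "c4nn(C6CCCC6)c5ncccc45", description: "1-cyclopentyl-triazolopyridinyl analogue"}
    - {label: R1g, smiles: "c4ccco4", description: "2-furyl"}
    - {label: R1h, smiles: "c4cccs4", description: "2-thienyl"}
    - {label: R1i, smiles: "c4cc[nH]n4", description: "1H-pyrazolyl"}
    - {label: R1j, smiles: "C4CCCCC4", description: "cyclohexyl"}
    - {label: R1k, smiles: "N4CCOCC4", description: "morpholino"}
    - {label: R1l, smiles: "c4ccn(C)c4", description: "1-methylpyrrolyl"}
    - {label: R1m, smiles: "c4nn(C6CCCC6)c5cccnc45", description: "1-cyclopentyl-pyrazolopyridinyl"}
  R2:
    - {label: R2a, smiles: "C", description: "methyl"}
    - {label: R2b, smiles: "C4CC4", description: "cyclopropyl"}
    - {label: R2c, smiles: "Cl", description: "chloro"}
    - {label: R2d, smiles: "C(F)(F)F", description: "trifluoromethyl"}
    - {label: R2e, smiles: "C=O", description: "formyl"}
    - {label: R2f, smiles: "CCC4CC4", description: "cyclopropylethyl"}
    - {label: R2g, smiles: "", description: "hydrogen"}
    - {label: R2h, smiles: "CC", description: "ethyl"}
    - {label: R2i, smiles: "N", description: "amino"}
  R3:
    - {label: R3a, smiles: "Cl", description: "chloro"}
    - {label: R3b, smiles: "N", description: "amino"}
    - {label: R3c, smiles: "C#N", description: "cyano"}
    - {label: R3d, smiles: "O", description: "hydroxyl"}
    - {label: R3e, smiles: "F", description: "fluoro"}
    - {label: R3f, smiles: "C", description: "methyl"}
    - {label: R3g, smiles: "CC", description: "ethyl"}
    - {label: R3h, smiles: "C(F)(F)F", description: "trifluoromethyl"}
    - {label: R3i, smiles: "OC", description: "methoxy"}
  R4:
    - {label: R4a, smiles: "N", description: "amino"}
    - {label: R4b, smiles: "C(C)C", description: "isopropyl"}
    - {label: R4c, smiles: "C(C)=O", description: "acetyl"}
    - {label: R4d, smiles: "CCO", description: "2-hydroxyethyl"}
    - {label: R4e, smiles: "CCC", description: "propyl"}
    - {label: R4f, smiles: "Cc4ccccc4", description: "benzyl"}
    - {label: R4g, smiles: "C", description: "methyl"}
    - {label: R4h, smiles: "C4CCCCC4", description: "cyclohexyl"}
    - {label: R4i, smiles: "C4CC4", description: "cyclopropyl"}
    - {label: R4j, smiles: "C4CCCC4", description: "cyclopentyl"}
    - {label: R4k, smiles: "", description: "hydrogen"}
combination:
  R1:
    - {label: R1-iPr, smiles: "c4nc5cc(F)ccc5n4C(C)C", description: "benzimidazole, N-isopropyl"}
    - {label: R1-cPr, smiles: "c4nc5cc(F)ccc5n4C6CC6", description: "benzimidazole, N-cyclopropyl"}
    - {label: R1-cPe, smiles: "c4nc5cc(F)ccc5n4C6CCCC6", description: "benzimidazole, N-cyclopentyl"}
  R2:
    - {label: R2-H, smiles: "", description: "hydrogen"}
    - {label: R2-F, smiles: "F", description: "fluoro"}
    - {label: R2-Me, smiles: "C", description: "methyl"}
  R3:
    - {label: R3-H, smiles: "", description: "hydrogen"}
    - {label: R3-F, smiles: "F", description: "fluoro"}
    - {label: R3-OMe, smiles: "OC", description: "methoxy"}
  R4:
    - {label: R4-H, smiles: "", description: "hydrogen"}
    - {label: R4-Me, smiles: "C", description: "methyl"}
    - {label: R4-iPr, smiles: "C(C)C", description: "isopropyl"}
variants:
  - tag: "A"
    pattern: ")Cc1ccc"
    replacement: ")c1ccc"
    description: >
      Deletion of the methylene linker between the piperazine and the
      aminopyridine ring.
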