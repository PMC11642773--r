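# Feature specification for the mu opioid receptor intracellular pocket.
# Torsion residue ranges cover the intracellular halves of the helices
# (G84(1.46)-D116(2.50), S156(3.39)-W194(4.50), P246(5.50)-F291(6.44),
# Y328(7.43)-F349(H8), Ballesteros-Weinstein superscripts in parentheses);
# ca_residues are the 22 positions at the middle/intracellular end of each
# helix and the middle of each intracellular loop. The hydrogen-bond
# donor/acceptor atom-name sets are a conventional polar-atom
# reconstruction (no curated atom list exists); candidates are enumerated
# from them and admitted by the 8.0 Angstrom reference-frame cutoff.
name: mor-intracellular
torsion_ranges:
  - {from: 84, to: 116}
  - {from: 156, to: 194}
  - {from: 246, to: 291}
  - {from: 328, to: 349}
torsion_angles: [phi, psi, chi1, chi2]
ca_residues: [84, 91, 99, 102, 105, 116, 156, 164, 170, 178, 183, 194,
              253, 260, 267, 271, 283, 291, 328, 338, 343, 349]
min_sequence_separation: 2
hbond:
  cutoff: 8.0
  reconstruction: true
  donor_atoms: [N, ND1, ND2, NE, NE1, NE2, NH1, NH2, NZ, OG, OG1, OH, SG]
  acceptor_atoms: [O, OD1, OD2, OE1, OE2, OG, OG1, OH, ND1, NE2, SD]
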