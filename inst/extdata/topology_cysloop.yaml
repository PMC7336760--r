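# Transmembrane topology registry for Cys-loop receptor subunits.
#
# Helix spans are data, not computation: they snapshot SwissProt
# TRANSMEM-style annotations of the canonical sequence and may differ by
# 1-2 residues between annotation releases. Orientations alternate
# out-in-out-in (N-terminal side of M1/M3 extracellular, M2/M4
# cytoplasmic), as in every Cys-loop subunit.
#
# The prime anchor pins the family-wide M2 prime numbering to the
# conserved 9' activation-gate leucine of GABA-A alpha-2 (Leu291), so the
# numbering does not depend on boundary-annotation drift.
flank: 5
proteins:
  GABRA2:
    accession: P47869
    helices:
      M1: {start: 252, end: 273, n_term_side: extracellular}
      M2: {start: 278, end: 299, n_term_side: cytoplasmic}
      M3: {start: 312, end: 333, n_term_side: extracellular}
      M4: {start: 424, end: 445, n_term_side: cytoplasmic}
anchors:
  GABRA2: {anchor_pos: 291, anchor_prime: 9}
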