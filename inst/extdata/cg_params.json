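{
  "version": "1.0",
  "comment": "Coarse-grained pseudoatom parameter table. Each residue is reduced to one Calpha bead plus 0-2 side-chain beads placed at the centroid of the listed heavy atoms. 'type' indexes the LJ-type table below; sigma is the pair-contact distance scale (Angstrom, combined arithmetically), eps the well-depth scale (combined geometrically). Charges sit on the last side-chain bead of charged residue types, in elementary charge units.",
  "types": {
    "CA":    {"sigma": 4.0, "eps": 0.20},
    "SC_S":  {"sigma": 4.2, "eps": 0.30},
    "SC_M":  {"sigma": 4.6, "eps": 0.30},
    "SC_L":  {"sigma": 5.0, "eps": 0.30},
    "BEAD":  {"sigma": 4.0, "eps": 0.30}
  },
  "residues": {
    "GLY": {"sc": []},
    "ALA": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0}]},
    "SER": {"sc": [{"atoms": ["CB", "OG"], "type": "SC_S", "charge": 0}]},
    "CYS": {"sc": [{"atoms": ["CB", "SG"], "type": "SC_S", "charge": 0}]},
    "THR": {"sc": [{"atoms": ["CB", "OG1", "CG2"], "type": "SC_S", "charge": 0}]},
    "VAL": {"sc": [{"atoms": ["CB", "CG1", "CG2"], "type": "SC_S", "charge": 0}]},
    "PRO": {"sc": [{"atoms": ["CB", "CG", "CD"], "type": "SC_S", "charge": 0}]},
    "ILE": {"sc": [{"atoms": ["CB", "CG1", "CG2", "CD1"], "type": "SC_M", "charge": 0}]},
    "LEU": {"sc": [{"atoms": ["CB", "CG", "CD1", "CD2"], "type": "SC_M", "charge": 0}]},
    "MET": {"sc": [{"atoms": ["CB", "CG"], "type": "SC_S", "charge": 0},
                   {"atoms": ["SD", "CE"], "type": "SC_M", "charge": 0}]},
    "ASN": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "OD1", "ND2"], "type": "SC_M", "charge": 0}]},
    "GLN": {"sc": [{"atoms": ["CB", "CG"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CD", "OE1", "NE2"], "type": "SC_M", "charge": 0}]},
    "ASP": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "OD1", "OD2"], "type": "SC_M", "charge": -1}]},
    "GLU": {"sc": [{"atoms": ["CB", "CG"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CD", "OE1", "OE2"], "type": "SC_M", "charge": -1}]},
    "LYS": {"sc": [{"atoms": ["CB", "CG", "CD"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CE", "NZ"], "type": "SC_M", "charge": 1}]},
    "ARG": {"sc": [{"atoms": ["CB", "CG", "CD"], "type": "SC_S", "charge": 0},
                   {"atoms": ["NE", "CZ", "NH1", "NH2"], "type": "SC_M", "charge": 1}]},
    "HIS": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "ND1", "CD2", "CE1", "NE2"], "type": "SC_M", "charge": 0}]},
    "PHE": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"], "type": "SC_L", "charge": 0}]},
    "TYR": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"], "type": "SC_L", "charge": 0}]},
    "TRP": {"sc": [{"atoms": ["CB"], "type": "SC_S", "charge": 0},
                   {"atoms": ["CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"], "type": "SC_L", "charge": 0}]}
  }
}
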