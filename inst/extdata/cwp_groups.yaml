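# Atom-name -> chemical-group table for cyclo-Trp-Pro molecules
# (PDB-style Trp/Pro naming), plus the aromatic ring definitions.
# Entries are matched in order; the first hit wins, which makes the
# indole N-H and aromatic carbons take precedence over the generic side
# chain so the labels form an exclusive partition.
groups:
  - {residue: TRP, name_pattern: "^(NE1|HE1)$",                        group: W_NH}
  - {residue: TRP, name_pattern: "^(CG|CD1|CD2|CE2|CE3|CZ2|CZ3|CH2)$", group: W_aro}
  - {residue: TRP, name_pattern: "^(CB|HB.*|HD1|HE3|HZ.*|HH2)$",       group: W_sc}
  - {residue: TRP, name_pattern: "^(N|H|HN|CA|HA|C|O|C1|O1)$",         group: W_mc}
  - {residue: PRO, name_pattern: "^(CB|CG|CD|HB.*|HG.*|HD.*)$",        group: P_sc}
  - {residue: PRO, name_pattern: "^(N|CA|HA|C|O|C1|O1)$",              group: P_mc}
  - {residue: "HOH|WAT|SOL", name_pattern: ".*",                       group: water}
rings:
  - {residue: TRP, kind: indole5, members: [CG, CD1, NE1, CE2, CD2]}
  - {residue: TRP, kind: indole6, members: [CD2, CE2, CZ2, CH2, CZ3, CE3]}
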