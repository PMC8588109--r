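# Synthetic example selection spec (not derived from any real structure):
# a 60-bead dendrimer with 8 charged terminals, 8 counterions and
# two planar triples on the same spacer.
atoms:
  - ids: "1-52"
    role: dendrimer
    element: C
    mass: 100
  - ids: "53-60"
    role: terminal_N
    element: N
    mass: 100
    charge: 1
  - ids: "61-68"
    role: counterion
    element: Cl
    mass: 35.45
    charge: -1
planar_groups:
  - group_id: 1
    triple: [1, 2, 3]
    center_atoms: [1, 2, 3]
    spacer_id: 1
  - group_id: 2
    triple: [4, 5, 6]
    center_atoms: [4, 5, 6]
    spacer_id: 1
donors: [53, 54]
hydrogens:
  - hydrogen: 55
    donor: 53
  - hydrogen: 56
    donor: 54
acceptors: [61, 62]
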