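# HIV LTR-III quadruplex-duplex annotation (28-nt intramolecular G4 with a
# duplex stem inside the diagonal loop). Tetrad membership is left empty on
# purpose: derive it from a structure with detectTetrads().
sequence: d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]
tetrads: []
loops:
- class: propeller
  from: 18
  to: 18
- class: V-shaped
  from: 25
  to: 26
- class: lateral
  from: 22
  to: 24
- class: diagonal
  from: 3
  to: 14
duplex_pairs:
- [5, 13]
- [6, 12]
- [11, 7]
junction: [4, 14]
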