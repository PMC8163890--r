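# Default exclusion-screening term lists (substring / term-id matching).
# transferable_AMR: mobile antibiotic-resistance determinants.
# virulence_factor: toxins and invasion factors incompatible with an LBP.
transferable_AMR:
  - vanA
  - vanB
  - "vancomycin resistance"
  - tetM
  - tetW
  - ermB
  - "beta-lactamase"
  - mecA
  - "aminoglycoside acetyltransferase"
  - "chloramphenicol acetyltransferase"
virulence_factor:
  - "Shiga toxin"
  - stx1
  - stx2
  - "fragilysin"
  - bft
  - "enterotoxin"
  - "cytolethal distending toxin"
  - "intimin"
  - "invasin"
  - "hemolysin"
  - "aerolysin"
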