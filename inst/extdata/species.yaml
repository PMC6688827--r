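# Editable residue-name -> species-class lookup and per-class headgroup
# particle names.  Load with read_species_table() and pass to
# load_structure() to override the built-in defaults.
residues:
  POPC: PC
  DOPC: PC
  DPPC: PC
  POPS: PS
  DOPS: PS
  POP4: PI4P
  PIP4: PI4P
  PI4P: PI4P
  POP2: PIP2
  PIP2: PIP2
  ION: ion
  "NA": ion
  CL: ion
  W: solvent
  SOL: solvent
  HOH: solvent
headgroups:
  PC: [NC3, PO4, HD, P]
  PS: [CNO, PO4, HD, P]
  PI4P: [PO4, C1, C2, C3, P1, P2, P3, P4, P5, HD, P]
  PIP2: [PO4, C1, C2, C3, P1, P2, P3, P4, P5, HD, P]
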