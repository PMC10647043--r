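chembl476099_synthetic_parent.smi
  SYNTHETIC stand-in for the histamine H3 receptor antagonist parent ligand
  (accession CHEMBL476099). The true structure requires a database lookup
  that this package deliberately never performs at test time; this
  reconstruction -- 6-(3-(piperidin-1-yl)propoxy)-N-methylnaphthalene-2-
  carboxamide -- carries the documented features of that parent: a
  2,6-disubstituted naphthalene core with two distinct non-aromatic
  substituents and no other aryl-aryl linker. Any parent with those features
  yields the same design-family size under exhaustive naphthalene-type
  azologization. Fields: SMILES <TAB> ligand_id <TAB> pAffinity.
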