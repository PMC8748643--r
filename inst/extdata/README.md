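# Bundled plain-text fixtures

- `ddaci_snp_matrix.tsv` — intraspecific SNP matrix of seven
  *Dipterophagus daci* mitogenome samples (10 variable positions in
  protein-coding genes), in the printed-matrix dialect read by
  `read_snp_matrix()`: reference row (`Bfra485`) fully filled, blank
  cell = same nucleotide as the reference, `.` = missing call (the
  low-coverage sample `Bn240`). The per-position alleles and per-sample
  allele counts follow the published matrix; the assignment of each
  sample's alleles to columns is a consistent reconstruction (the
  flat-text source does not preserve the column layout), so only
  column-level facts (positions, reference alleles, per-sample counts,
  gene assignment, SNP total) should be asserted against it.
- `ddaci_pcg_annotation_synthetic.tsv` — SYNTHETIC stand-in annotation
  for the four protein-coding genes harbouring those SNPs (cox1, nad5,
  nad4, cob). Coordinates are plausible for an insect mitogenome and
  chosen so each published SNP position falls inside its published
  gene; they are not the deposited record's coordinates.
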