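Place user-supplied reference data here to enable the two comparisons
against published results:

  8fkc.pdb 8fkd.pdb 8fke.pdb 8fkf.pdb 8fkg.pdb 6oni.pdb
      Deposited coordinate files (PDB format) for the corepressor-peptide
      co-crystal structures and the reference inverse-agonist structure.
      Download from https://www.rcsb.org; they are not redistributed with
      this package.

  profiling.csv
      Published per-compound source table with a weighted_shift_H column
      plus the functional profiling readouts (one row per compound).

Nothing in this directory is required for the synthetic-data analyses or
the rest of the test suite.
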