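# External data drop-in

The statistics-parity and full-pipeline acceptance checks operate on the
deposited mitochondrial COI alignment (GenBank accessions
LC224174-LC224278 and LC474498-LC474506, trimmed to the common 608 bp,
79 sequences). That alignment is not redistributed with the package. To
enable those checks, place here before installing:

* `haustorioides_coi.fasta` — the aligned sequences (A/C/G/T/N/- only,
  equal lengths);
* `haustorioides_coi_pops.tsv` — two tab-separated columns mapping each
  sequence label to its population (`NWP` for the 64 northwestern Pacific
  individuals, `Tohoku` for the 15 individuals from sampling site 7).

Without these files the two checks fail with a message saying the data
are absent; every other test runs on synthetic data generated in code.
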