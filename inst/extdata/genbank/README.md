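# Real-data input slot

The published-table acceptance checks expect two user-supplied files
here (they are not redistributed with the package):

* `cytb.fasta` — full cytochrome-b CDS of cow (EU177848),
  deer (AB210267) and hippopotamus (NC_000889), records named
  `cow`, `deer`, `hippo`.
* `nd2.fasta` — full NADH dehydrogenase subunit 2 CDS of the same
  accessions, same record names.

Sequences must be plain A/C/G/T (no ambiguity codes). The analysis code
trims each CDS to its 5'-terminal 1,038 bp after dropping the initiation
codon (`trim5Prime()`) and translates with the vertebrate mitochondrial
code (`translateMito()`).
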