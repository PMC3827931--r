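# scale: rna_vdw (per-base Van der Waals contact propensity)
# source: SYNTHETIC stand-in; see rna_hbond_synthetic.tsv for provenance
# notes. Provisional defaults encoding the purine > pyrimidine trend only.
residue	value
A	0.90
C	0.70
G	1.00
U	0.75
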