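# scale: rna_hbond (per-base hydrogen-bonding contact propensity)
# source: SYNTHETIC stand-in. The published method derives these values from
# purine/pyrimidine contact statistics over 41 RNA-protein complexes, but the
# numbers themselves are not printed anywhere retrievable offline. The values
# below only encode the qualitative purine > pyrimidine contact trend and are
# provisional defaults; replace this file with measured propensities for
# production use. Correctness of the pipeline never depends on these values.
residue	value
A	0.80
C	0.55
G	1.00
U	0.65
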