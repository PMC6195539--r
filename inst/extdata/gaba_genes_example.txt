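# Example GABA-system gene set (one symbol per line).
# Placeholder list for demonstrations: the genes of the bundled
# homozygous-variant table plus canonical GABA synthesis, transport and
# receptor genes. Substitute your own curated pathway list for real use.
ADCY3
ADCY8
GABRP
HSPA8
CNTNAP4
HAP1
GAD1
GAD2
ABAT
ALDH5A1
GABBR1
GABBR2
GABRA1
GABRA2
GABRA3
GABRA4
GABRA5
GABRB1
GABRB2
GABRB3
GABRG1
GABRG2
GABRG3
GABRD
GABRE
GABRR1
GABRR2
SLC6A1
SLC6A11
SLC6A12
SLC6A13
SLC32A1
GPHN
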