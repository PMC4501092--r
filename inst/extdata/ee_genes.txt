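# Epigenetic-enzyme (chromatin/DNA-methylation writer, reader, eraser, editor)
# gene symbols; one per line.
UHRF1
WHSC1
CBX7
EYA4
EZH2
SETBP1
PRDM2
PRDM5
DUSP1
KAT2B
RAD54L
PCNA
TTF2
KDM1A
SUV39H2
HDAC1
TDG
TET3
DNMT1
DNMT3A
DNMT3B
TET1
TET2
IDH1
IDH2
EZH1
HDAC2
HDAC3
HDAC4
HDAC8
HDAC10
SIRT1
SETD3
SMARCB1
ZBTB4
ZBTB33
KAT5
KAT2A
PRMT1
PRMT5
NCOA1
NCOA2
NCOA4
NCOA7
MBD1
MBD2
MBD3
MBD4
MECP2
CHD1
CHD3
CHD4
KDM2A
KDM3A
KDM4A
KDM5A
KDM6A
KMT2A
KMT2C
SETDB1
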