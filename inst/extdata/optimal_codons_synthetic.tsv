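codon	optimal
AAA	FALSE
AAC	TRUE
AAG	TRUE
AAT	FALSE
ACA	FALSE
ACC	TRUE
ACG	FALSE
ACT	FALSE
AGA	FALSE
AGC	TRUE
AGG	FALSE
AGT	FALSE
ATA	FALSE
ATC	TRUE
ATG	TRUE
ATT	FALSE
CAA	FALSE
CAC	TRUE
CAG	TRUE
CAT	FALSE
CCA	FALSE
CCC	TRUE
CCG	FALSE
CCT	FALSE
CGA	FALSE
CGC	TRUE
CGG	FALSE
CGT	TRUE
CTA	FALSE
CTC	FALSE
CTG	TRUE
CTT	FALSE
GAA	FALSE
GAC	TRUE
GAG	TRUE
GAT	FALSE
GCA	FALSE
GCC	TRUE
GCG	FALSE
GCT	FALSE
GGA	FALSE
GGC	TRUE
GGG	FALSE
GGT	TRUE
GTA	FALSE
GTC	TRUE
GTG	TRUE
GTT	FALSE
TAC	TRUE
TAT	FALSE
TCA	FALSE
TCC	TRUE
TCG	FALSE
TCT	FALSE
TGC	TRUE
TGG	TRUE
TGT	FALSE
TTA	FALSE
TTC	TRUE
TTG	FALSE
TTT	FALSE
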