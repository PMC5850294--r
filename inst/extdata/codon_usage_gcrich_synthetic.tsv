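# synthetic GC-rich codon usage: codon weight 3^(number of G/C bases)
AAA 1
AAC 3
AAG 3
AAT 1
ACA 3
ACC 9
ACG 9
ACT 3
AGA 3
AGC 9
AGG 9
AGT 3
ATA 1
ATC 3
ATG 3
ATT 1
CAA 3
CAC 9
CAG 9
CAT 3
CCA 9
CCC 27
CCG 27
CCT 9
CGA 9
CGC 27
CGG 27
CGT 9
CTA 3
CTC 9
CTG 9
CTT 3
GAA 3
GAC 9
GAG 9
GAT 3
GCA 9
GCC 27
GCG 27
GCT 9
GGA 9
GGC 27
GGG 27
GGT 9
GTA 3
GTC 9
GTG 9
GTT 3
TAA 0
TAC 3
TAG 0
TAT 1
TCA 3
TCC 9
TCG 9
TCT 3
TGA 0
TGC 9
TGG 9
TGT 3
TTA 1
TTC 3
TTG 3
TTT 1
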