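trinucleotide	frequency
ACA	0.04498135
ACC	0.03264528
ACG	0.00668992
ACT	0.02580082
ATA	0.02943177
ATC	0.04087258
ATG	0.03144158
ATT	0.0446298
CCA	0.02780633
CCC	0.03392567
CCG	0.00698232
CCT	0.02917568
CTA	0.04047195
CTC	0.02635491
CTG	0.03380764
CTT	0.02611283
GCA	0.03604501
GCC	0.02452699
GCG	0.01122879
GCT	0.03095166
GTA	0.03768901
GTC	0.0305059
GTG	0.045144
GTT	0.04325169
TCA	0.0449778
TCC	0.02571521
TCG	0.00935751
TCT	0.03458031
TTA	0.04460814
TTC	0.03190397
TTG	0.03853507
TTT	0.02984851
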