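amino_acid	codon	rscu
Ala	GCU	1.06
Ala	GCG	0.438
Ala	GCC	1.39
Ala	GCA	1.113
Arg	AGA	1.025
Arg	AGG	0.975
Arg	CGA	1.379
Arg	CGC	0.944
Arg	CGG	0.702
Arg	CGU	0.975
Asn	AAC	1.087
Asn	AAU	0.913
Asp	GAU	0.966
Asp	GAC	1.034
Cys	UGU	0.81
Cys	UGC	1.19
Gln	CAA	0.962
Gln	CAG	1.038
Glu	GAG	0.837
Glu	GAA	1.163
Gly	GGU	0.972
Gly	GGG	0.536
Gly	GGC	0.948
Gly	GGA	1.544
His	CAC	1.111
His	CAU	0.889
Ile	AUU	1.074
Ile	AUA	0.69
Ile	AUC	1.236
Leu	CUA	0.365
Leu	CUC	1.335
Leu	CUG	1.334
Leu	CUU	0.967
Leu	UUA	0.546
Leu	UUG	1.454
Lys	AAA	0.981
Lys	AAG	1.019
Met	AUG	1
Phe	UUU	0.915
Phe	UUC	1.085
Pro	CCA	1.16
Pro	CCC	0.883
Pro	CCU	1.134
Pro	CCG	0.823
Ser	UCG	0.907
Ser	UCU	1.062
Ser	UCA	0.957
Ser	UCC	1.074
Ser	AGC	1.061
Ser	AGU	0.939
Thr	ACC	1.134
Thr	ACA	0.938
Thr	ACG	0.895
Thr	ACU	1.032
Trp	UGG	1
Tyr	UAC	1.15
Tyr	UAU	0.85
Val	GUU	1.12
Val	GUG	1.029
Val	GUC	1.409
Val	GUA	0.442
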