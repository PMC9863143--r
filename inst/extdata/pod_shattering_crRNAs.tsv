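id	protospacer	pam	contig	start	end	subroi
gRNA.1	CTCAAGGGTCGTAACATTCC	TGG	Chr05	38489481	38489500	1
gRNA.2	TATGATGACACACACGTTAA	CGG	Chr05	38540913	38540894	1
gRNA.3	ATGCCATTAAGAGTTGCGAT	GGG	Chr05	38537240	38537259	2
gRNA.4	TTTTCACGACTTTGCATCTT	TGG	Chr05	38582350	38582331	2
gRNA.5	AGAACGGAAGGAATGGGACA	GGG	Chr05	38580180	38580199	3
gRNA.6	GGATATTACAAACAGACGAA	AGG	Chr05	38628876	38628857	3
gRNA.7	ACTGTTGCGTAGGGACAAAT	CGG	Chr05	38626429	38626448	4
gRNA.8	AGTTTGACAACTATCCCAAG	GGG	Chr05	38674838	38674819	4
gRNA.9	GCCACTATAGTGCCAACTTC	TGG	Chr05	38671239	38671258	5
gRNA.10	ATTACCGTAGCTAGTTATTA	AGG	Chr05	38723776	38723757	5
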