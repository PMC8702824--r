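# Informative-SNP support counts per embryo for the carrier parent's two
# haplotypes in the two PGT-M families. support0 = SNPs consistent with the
# disease-linked haplotype (F0 in family 5, M0 in family 8), support1 = SNPs
# consistent with the normal haplotype. Family 8 embryo 8 was used to
# construct the parental haplotypes and has no counts.
family	embryo	support0	support1	reported_genotype
5	1	0	35	normal
5	2	32	0	heterozygous
5	3	0	28	normal
5	4	1	26	normal
5	5	1	23	normal
5	6	0	30	normal
5	7	31	2	heterozygous
5	8	35	0	heterozygous
8	1	60	2	heterozygous
8	2	0	78	normal
8	3	0	80	normal
8	4	0	83	normal
8	5	1	74	normal
8	6	70	0	heterozygous
8	7	4	71	normal
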