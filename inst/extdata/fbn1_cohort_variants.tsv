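# FBN1 (NM_000138.5) variants identified in 11 Marfan-syndrome families.
family_id	hgvs_c	hgvs_p	exon
1	c.4955G>A	p.(Cys1652Tyr)	41
2	c.4469A>C	p.(Glu1490Ala)	37
3	c.4210+1G>A	p.(?)	NA
4	c.7559C>T	p.(Thr2520Met)	61
5	c.6615A>G	p.(Glu2205=)	54
6	c.3244G>T	p.(Gly1082Cys)	27
7	c.5885_5895del	p.(Tyr1962Serfs*11)	48
8	c.5498G>T	p.(Cys1833Phe)	45
9	c.6695G>T	p.(Cys2232Phe)	55
10	c.364C>T	p.(Arg122Cys)	5
11	c.3602G>A	p.(Cys1201Tyr)	30
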