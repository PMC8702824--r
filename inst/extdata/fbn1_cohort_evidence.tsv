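# ACMG/AMP evidence assignments and reported classifications for the 11
# FBN1 variants of the Marfan cohort. Evidence codes may carry an applied
# strength (e.g. PS4_Moderate). reported_class is the classification as
# assigned by the original curators; the rules engine reproduces 10 of 11
# (see package tests for the documented divergence at c.3244G>T).
variant_key	evidence	reported_class
c.4955G>A	PM1;PM2;PS4_Moderate;PP1_Moderate;PP2;PP3;PP4	likely_pathogenic
c.4469A>C	PM2;PM1;PM5;PP1;PP2;PP3	likely_pathogenic
c.4210+1G>A	PVS1;PM2;PM6;PS4_Supporting	pathogenic
c.7559C>T	BS4;PS4_Supporting;PM2;PP2	uncertain_significance
c.6615A>G	PM2;PP1;PP3;PP4	uncertain_significance
c.3244G>T	PM1;PM2;PP3;PP2;PP1_Strong	likely_pathogenic
c.5885_5895del	PVS1;PM2;PP4	pathogenic
c.5498G>T	PM1;PM2;PP2;PP3;PM5_Strong;PP4	pathogenic
c.6695G>T	PM1;PM2;PP2;PP3;PM5_Strong	pathogenic
c.364C>T	PM1;PM2;PS4_Moderate;PP2;PP3;PP4;PP1_Strong	pathogenic
c.3602G>A	PM1;PM2;PM6;PP2;PS4_Moderate;PP3	likely_pathogenic
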