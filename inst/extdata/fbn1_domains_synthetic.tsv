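# Synthetic, simplified domain map of human fibrillin-1 (FBN1, 2871 aa).
# This is NOT a faithful per-module annotation: real fibrillin-1 alternates
# 47 EGF-like modules (43 calcium-binding) with TB/8-cysteine and hybrid
# modules. Here neighbouring cbEGF modules are merged into coarse blocks
# wide enough to label the residues this package's examples touch; residues
# outside every block are reported as "other".
# Note: residue 2520 (Thr2520) is labelled cbEGF here, following the variant
# table this map accompanies; some published domain annotations place it in
# a TB/hybrid region instead.
domain_label	start	end
non_cbEGF	45	165
cbEGF	1028	1270
cbEGF	1360	1700
cbEGF	1800	2010
cbEGF	2100	2300
cbEGF	2490	2560
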