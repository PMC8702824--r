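1 I-1 0 0 1 2 2
1 I-2 0 0 2 1 1
1 II-1 I-1 I-2 1 2 2
1 II-2 I-1 I-2 2 2 2
1 II-3 I-1 I-2 1 2 2
1 II-4 I-1 I-2 2 2 2
1 II-5 0 0 1 1 1
2 I-1 0 0 2 2 2
2 I-2 0 0 1 2 2
2 II-1 0 0 1 1 1
2 II-2 I-2 I-1 2 2 2
2 II-3 I-2 I-1 2 2 2
2 II-4 0 0 1 1 1
5 I-1 0 0 1 2 2
5 I-2 0 0 2 1 1
5 II-1 0 0 1 1 1
5 II-2 I-1 I-2 2 2 2
5 II-3 I-1 I-2 2 1 1
5 III-1 0 0 1 1 1
5 III-2 II-1 II-2 2 2 2
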