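# toy exp-6 force field for the example run
types C O
pair C C 369743 3.60 2439.8
pair O O 284623 3.96 1334.7
rank 0
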