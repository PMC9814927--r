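2
carbon monoxide toy
C -0.6 0 0 0.02 C
O 0.6 0 0 -0.02 O
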