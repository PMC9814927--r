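molecules:
  CO: co.xyz
forcefield: toy.ff
schedule: {increment: 5, n_lids: 2, steps_per_lid: 25}
moves: {translation: 0.5, rotation: 0.05}
settings: {gtol: 1.0e-3}
criteria: {pattern_threshold: 0.9}
seed: 1
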