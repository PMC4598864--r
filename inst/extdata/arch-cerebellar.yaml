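# Cerebellum-like bifurcating architecture: input + common AP-50 layer,
# main branch at AP 25 ending in an inhibitory link onto the deep layer,
# direct side branch mixed at a main:side combination ratio of 1:2.
layers:
- layer: 1
  'n': 144
- layer: 2
  'n': 1000
  ap: 50
- layer: 3
  'n': 1000
  ap: 25
- layer: 4
  'n': 1000
  ap: 25
- layer: 5
  'n': 1000
  ap: 25
- layer: 6
  'n': 1000
  ap: 25
edges:
- {from: 1, to: 2, polarity: 1, ratio: 1}
- {from: 2, to: 3, polarity: 1, ratio: 1}
- {from: 3, to: 4, polarity: 1, ratio: 1}
- {from: 4, to: 5, polarity: 1, ratio: 1}
- {from: 5, to: 6, polarity: -1, ratio: 1}
- {from: 3, to: 6, polarity: 1, ratio: 2}
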