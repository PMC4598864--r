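# Basal-ganglia-like architecture: cortex-like AP-50 layer, then
# striatum- (AP 25), pallidum- (AP 10), nigra- (AP 25) and thalamus-like
# (AP 25) layers chained by inhibitory links, with a direct-pathway side
# branch mixed at a main:side combination ratio of 1:2.
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
  ap: 10
- layer: 5
  'n': 1000
  ap: 25
- layer: 6
  'n': 1000
  ap: 25
edges:
- {from: 1, to: 2, polarity: 1, ratio: 1}
- {from: 2, to: 3, polarity: 1, ratio: 1}
- {from: 3, to: 4, polarity: -1, ratio: 1}
- {from: 4, to: 5, polarity: -1, ratio: 1}
- {from: 3, to: 5, polarity: -1, ratio: 2}
- {from: 5, to: 6, polarity: -1, ratio: 1}
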