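{
  "constant": {
    "label": "constant size",
    "theta": 5,
    "epochs": [{"time": 0, "size": 1}]
  },
  "ancient_expansion": {
    "label": "ancient expansion (10x growth at 0.5 coalescent units)",
    "theta": 5,
    "epochs": [{"time": 0, "size": 1}, {"time": 0.5, "size": 0.1}]
  },
  "bottleneck_expansion": {
    "label": "bottleneck then expansion",
    "theta": 5,
    "epochs": [{"time": 0, "size": 1}, {"time": 0.2, "size": 0.05}, {"time": 0.6, "size": 0.5}]
  },
  "repeated_bottleneck": {
    "label": "repeated bottlenecks",
    "theta": 5,
    "epochs": [{"time": 0, "size": 1}, {"time": 0.2, "size": 0.1},
               {"time": 0.4, "size": 1}, {"time": 0.6, "size": 0.1},
               {"time": 0.8, "size": 1}]
  }
}
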