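{
  "description": "Planted deposit-accumulation effect factors for the simulated CSF1R-inhibitor trial re-enactments (treated margin deposit intensity = factor * control intensity).",
  "femri_clusters": {
    "treatment_factor": 0.37,
    "endpoint": "high-iron FeMRI pixel clusters, treated as % of control",
    "expected_percent_of_control": 37
  },
  "ts1_pb": {
    "treatment_factor": 0.50,
    "endpoint": "TS1 Prussian-blue iron deposit counts, % reduction",
    "expected_percent_reduction": 50
  },
  "ln99_pb": {
    "treatment_factor": 0.15,
    "endpoint": "99LN Prussian-blue iron deposit counts, % reduction",
    "expected_percent_reduction": 85
  }
}
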