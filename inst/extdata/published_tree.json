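{
  "format": "modytree/decision_tree",
  "version": 1,
  "steps": [
    {
      "target_group": "T1D",
      "markers": [
        "c_peptide"
      ],
      "weights": [
        1
      ],
      "threshold": 0.6,
      "direction": "lower_is_positive"
    },
    {
      "target_group": "T2D",
      "markers": [
        "c_peptide",
        "bmi"
      ],
      "weights": [
        1,
        0.16
      ],
      "threshold": 6.29,
      "direction": "higher_is_positive"
    },
    {
      "target_group": "HNF1A",
      "markers": [
        "ag15",
        "hscrp"
      ],
      "weights": [
        1,
        1.56
      ],
      "threshold": 10.16,
      "direction": "lower_is_positive"
    }
  ],
  "terminal_pair": [
    "HNF1A",
    "GCK"
  ],
  "candidate_markers": [
    "ag15",
    "hscrp",
    "bmi",
    "fasting_glucose",
    "c_peptide"
  ],
  "alpha": 0.05
}
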