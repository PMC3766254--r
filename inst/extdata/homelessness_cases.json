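{
  "cases": [
    {
      "label": "Case 1: most likely to result in homelessness",
      "activations": {
        "Addiction": 0.65,
        "Family Breakdown": 0.57,
        "Government Assistance": 0.46,
        "Mental Illness": 0.61
      }
    },
    {
      "label": "Case 2: least likely to result in homelessness",
      "activations": {
        "Addiction": 0.30,
        "Social Support Network": 0.61,
        "Education": 1.0,
        "Family Breakdown": 0.30,
        "Income": 0.72
      }
    },
    {
      "label": "Case 3: uncertain outcome of homelessness",
      "activations": {
        "Addiction": 0.20,
        "Social Support Network": 0.11,
        "Education": 0.94,
        "Family Breakdown": 0.51,
        "Income": 1.0
      }
    }
  ],
  "settings": {
    "threshold": "tanh",
    "epsilon": 1e-05,
    "max_iter": 100,
    "self_memory": 1
  }
}
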