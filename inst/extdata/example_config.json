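{
  "seed": 1,
  "cohorts": [
    {"cohort": "young", "n": 21},
    {"cohort": "elderly", "n": 23},
    {"cohort": "neglect", "n": 11,
     "starting_level": 2,
     "config": {"targets_per_round": 8, "n_rounds": 10,
                "speed_floor_override": 0.1}}
  ],
  "analysis": {"plateau_tolerance": 1}
}
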