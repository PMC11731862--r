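{
  "name": "csew",
  "n_default": 1232,
  "cluster_rate": 0,
  "marginals_are_percent": true,
  "marginals": {
    "sv_type": {"other_sv": 67.6, "rape": 32.4},
    "perpetrator": {"domestic": 24.6, "acquaintance": 33.2, "stranger_unknown": 42.2},
    "injury": {"no_injury": 60.9, "injury": 39.1},
    "gender": {"female": 90.4, "male": 9.6},
    "relationship_status": {"married_cohabiting": 21.7, "single_widowed": 57.0, "separated_divorced": 21.4},
    "ethnicity": {"white": 91.6, "non_white": 8.4},
    "employment": {"employed": 56.4, "unemployed": 7.6, "outside_labour_force": 30.4, "student": 5.6},
    "tenure": {"homeowner": 34.6, "renter": 59.8, "other": 5.6},
    "age": {"mean": 32.9, "sd": 12.4, "min": 16},
    "dependants": {"mean": 0.6, "sd": 1.0}
  }
}
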