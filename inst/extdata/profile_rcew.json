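{
  "name": "rcew",
  "n_default": 6102,
  "cluster_rate": 0,
  "marginals_are_percent": true,
  "marginals": {
    "sv_type": {"other_sv": 29.3, "rape": 70.7},
    "perpetrator": {"domestic": 48.2, "acquaintance": 40.2, "stranger_unknown": 11.6},
    "injury": {"no_injury": 94.0, "injury": 6.0},
    "gender": {"female": 92.1, "male": 7.9},
    "relationship_status": {"married_cohabiting": 16.8, "single_widowed": 71.7, "separated_divorced": 11.6},
    "ethnicity": {"white": 91.0, "non_white": 9.0},
    "employment": {"employed": 35.2, "unemployed": 38.2, "outside_labour_force": 11.7, "student": 14.9},
    "tenure": {"homeowner": 41.8, "renter": 18.4, "other": 39.7},
    "age": {"mean": 34.1, "sd": 12.9, "min": 16},
    "dependants": {"mean": 0.8, "sd": 1.2}
  }
}
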