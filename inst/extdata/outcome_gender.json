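{
  "outcome": "gender",
  "family": "bernoulli",
  "comment": "Generative coefficients: published donor-survey logistic column for gender (male = 1).",
  "beta": {
    "(Intercept)": -3.600,
    "sv_type=rape": -0.840,
    "perpetrator=acquaintance": 0.700,
    "perpetrator=stranger_unknown": 1.130,
    "injury=injury": 0.345,
    "relationship_status=single_widowed": -0.047,
    "relationship_status=separated_divorced": -1.494,
    "ethnicity=non_white": 0.247,
    "employment=unemployed": 0.540,
    "employment=outside_labour_force": -0.214,
    "employment=student": -0.098,
    "tenure=renter": 0.424,
    "tenure=other": 0.786,
    "dependants": -0.786,
    "age": 0.024
  },
  "gamma": {}
}
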