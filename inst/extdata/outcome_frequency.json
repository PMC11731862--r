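{
  "outcome": "frequency",
  "family": "count_negbin",
  "comment": "Generative coefficients: published donor-survey negative-binomial column for frequency of abuse; dispersion alpha = exp(lnalpha), var = mu + alpha*mu^2.",
  "beta": {
    "(Intercept)": 1.135,
    "sv_type=rape": -0.585,
    "perpetrator=acquaintance": -1.560,
    "perpetrator=stranger_unknown": -2.764,
    "gender=male": -0.539,
    "injury=injury": 0.313,
    "relationship_status=single_widowed": -0.531,
    "relationship_status=separated_divorced": 0.046,
    "ethnicity=non_white": -0.869,
    "employment=unemployed": 0.129,
    "employment=outside_labour_force": 0.148,
    "employment=student": 0.593,
    "tenure=renter": 0.086,
    "tenure=other": 0.083,
    "dependants": -0.041,
    "age": 0.017
  },
  "gamma": {},
  "lnalpha": 2.166
}
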