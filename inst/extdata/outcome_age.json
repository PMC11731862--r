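{
  "outcome": "age",
  "family": "gaussian",
  "comment": "Generative coefficients: published donor-survey OLS column for age; sigma chosen to match that fit's standard-error scale (residual sd ~ 11 years).",
  "beta": {
    "(Intercept)": 39.097,
    "sv_type=rape": -1.949,
    "perpetrator=acquaintance": -0.127,
    "perpetrator=stranger_unknown": -1.658,
    "gender=male": 2.831,
    "injury=injury": 0.531,
    "relationship_status=single_widowed": -5.234,
    "relationship_status=separated_divorced": 7.999,
    "ethnicity=non_white": 0.382,
    "employment=unemployed": -2.299,
    "employment=outside_labour_force": 4.033,
    "employment=student": -6.385,
    "tenure=renter": -4.351,
    "tenure=other": -9.545,
    "dependants": -2.486
  },
  "gamma": {},
  "sigma2": 121.0
}
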