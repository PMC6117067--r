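{
  "convention": "Weibull S(t) = exp(-(t/scale)^shape); months",
  "note": "Hazard ratios and response probabilities follow the published multivariate trial analysis. Baseline Weibulls and the response-time / loss-of-response submodels are package CALIBRATION values (the underlying patient-level fits are not public), chosen once so that simulated medians sit near the published arm-level medians.",
  "version": "1.0",
  "baseline_tp": {"shape": 1.3, "scale": 6.0},
  "baseline_td": {"shape": 1.1, "scale": 5.0},
  "baseline_os": {"shape": 1.1, "scale": 11.9},
  "response_time": {"meanlog": 0.7884573603642703, "sdlog": 0.45},
  "loss_of_response_time": {"shape": -0.04, "rate": 0.05},
  "response_prob": {
    "treatment": {"poor": 0.25, "favorable": 0.25, "intermediate": 0.25},
    "comparator": {"poor": 0.05, "favorable": 0.05, "intermediate": 0.05}
  },
  "hr_table": {
    "progression": {"response": 0.40, "favorable": 0.63, "intermediate": 0.79, "treat_early": 1.19, "treat_late": 0.88},
    "discontinuation": {"response": 0.18, "post_response": 1.34, "favorable": 0.64, "intermediate": 0.79, "treat": 0.73},
    "death": {"response": 0.06, "post_response": 0.49, "favorable": 0.29, "intermediate": 0.61, "treat_early": 0.50, "treat_late": 0.94}
  },
  "inflection": 3
}
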