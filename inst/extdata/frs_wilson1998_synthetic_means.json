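{
  "_comment": "Sex-specific categorized Framingham CHD risk equations. Coefficients and 10-year baseline survivals are the published Wilson 1998 values. The reference means are SYNTHETIC stand-ins (plausible values for a white middle-aged cohort of the 1970s); the originally published reference means are not redistributed in this package. Supply your own file via read_coefficient_set() to use authentic means.",
  "female": {
    "sex": "female",
    "provenance": "wilson1998",
    "means_provenance": "synthetic_reference_means",
    "terms": {
      "age": 0.33766,
      "age_sq": -0.00268,
      "tc_<160": -0.26138,
      "tc_200-239": 0.20771,
      "tc_240-279": 0.24385,
      "tc_>=280": 0.53513,
      "hdl_<35": 0.84312,
      "hdl_35-44": 0.37796,
      "hdl_45-49": 0.19785,
      "hdl_>=60": -0.42951,
      "bp_optimal": -0.53363,
      "bp_high_normal": -0.06773,
      "bp_stage1": 0.26288,
      "bp_stage2_4": 0.46573,
      "diabetes": 0.59626,
      "smoking_current": 0.29246
    },
    "means": {
      "age": 49.1,
      "age_sq": 2488.25,
      "tc_<160": 0.13,
      "tc_200-239": 0.29,
      "tc_240-279": 0.14,
      "tc_>=280": 0.06,
      "hdl_<35": 0.05,
      "hdl_35-44": 0.17,
      "hdl_45-49": 0.12,
      "hdl_>=60": 0.35,
      "bp_optimal": 0.26,
      "bp_high_normal": 0.20,
      "bp_stage1": 0.18,
      "bp_stage2_4": 0.08,
      "diabetes": 0.04,
      "smoking_current": 0.38
    },
    "baseline": {
      "value": 0.96246,
      "horizon": 10,
      "method": "cox_at_means"
    }
  },
  "male": {
    "sex": "male",
    "provenance": "wilson1998",
    "means_provenance": "synthetic_reference_means",
    "terms": {
      "age": 0.04826,
      "tc_<160": -0.65945,
      "tc_200-239": 0.17692,
      "tc_240-279": 0.50539,
      "tc_>=280": 0.65713,
      "hdl_<35": 0.49744,
      "hdl_35-44": 0.24310,
      "hdl_50-59": -0.05107,
      "hdl_>=60": -0.48660,
      "bp_optimal": -0.00226,
      "bp_high_normal": 0.28320,
      "bp_stage1": 0.52168,
      "bp_stage2_4": 0.61859,
      "diabetes": 0.42839,
      "smoking_current": 0.52337
    },
    "means": {
      "age": 48.6,
      "tc_<160": 0.13,
      "tc_200-239": 0.28,
      "tc_240-279": 0.11,
      "tc_>=280": 0.04,
      "hdl_<35": 0.19,
      "hdl_35-44": 0.36,
      "hdl_50-59": 0.17,
      "hdl_>=60": 0.11,
      "bp_optimal": 0.18,
      "bp_high_normal": 0.21,
      "bp_stage1": 0.24,
      "bp_stage2_4": 0.10,
      "diabetes": 0.05,
      "smoking_current": 0.40
    },
    "baseline": {
      "value": 0.90015,
      "horizon": 10,
      "method": "cox_at_means"
    }
  }
}
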