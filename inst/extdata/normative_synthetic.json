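{
  "description": "SYNTHETIC normative table for demonstration and testing. Strata are keyed by age band and years-of-education band; statistics are plausible raw-scale means and standard deviations, not published population norms.",
  "synthetic": true,
  "strata": [
    {"instrument": "MoCA", "subscore": "total", "age_band": "50-64", "education_band": "0-4", "mean": 21, "sd": 4},
    {"instrument": "MoCA", "subscore": "total", "age_band": "50-64", "education_band": "5-12", "mean": 24, "sd": 3.5},
    {"instrument": "MoCA", "subscore": "total", "age_band": "50-64", "education_band": "13+", "mean": 26, "sd": 3},
    {"instrument": "MoCA", "subscore": "total", "age_band": "65-80", "education_band": "0-4", "mean": 19, "sd": 4.5},
    {"instrument": "MoCA", "subscore": "total", "age_band": "65-80", "education_band": "5-12", "mean": 22, "sd": 4},
    {"instrument": "MoCA", "subscore": "total", "age_band": "65-80", "education_band": "13+", "mean": 24, "sd": 3.5},

    {"instrument": "FCSRT", "subscore": "immediate_memory", "age_band": "50-64", "education_band": "5-12", "mean": 30, "sd": 6},
    {"instrument": "FCSRT", "subscore": "immediate_memory", "age_band": "65-80", "education_band": "5-12", "mean": 26, "sd": 7},
    {"instrument": "FCSRT", "subscore": "delayed_recall", "age_band": "50-64", "education_band": "5-12", "mean": 11, "sd": 2.5},
    {"instrument": "FCSRT", "subscore": "delayed_recall", "age_band": "65-80", "education_band": "5-12", "mean": 9, "sd": 3},

    {"instrument": "WAIS_III", "subscore": "digit_symbol_coding", "age_band": "50-64", "education_band": "5-12", "mean": 55, "sd": 14},
    {"instrument": "WAIS_III", "subscore": "digit_symbol_coding", "age_band": "65-80", "education_band": "5-12", "mean": 42, "sd": 13},
    {"instrument": "WAIS_III", "subscore": "symbol_search", "age_band": "50-64", "education_band": "5-12", "mean": 26, "sd": 8},
    {"instrument": "WAIS_III", "subscore": "symbol_search", "age_band": "65-80", "education_band": "5-12", "mean": 20, "sd": 7},
    {"instrument": "WAIS_III", "subscore": "vocabulary", "age_band": "50-64", "education_band": "5-12", "mean": 35, "sd": 10},
    {"instrument": "WAIS_III", "subscore": "vocabulary", "age_band": "65-80", "education_band": "5-12", "mean": 33, "sd": 10},

    {"instrument": "VerbalFluency", "subscore": "phonemic_semantic", "age_band": "50-64", "education_band": "5-12", "mean": 45, "sd": 11},
    {"instrument": "VerbalFluency", "subscore": "phonemic_semantic", "age_band": "65-80", "education_band": "5-12", "mean": 38, "sd": 10},

    {"instrument": "ToulousePieron", "subscore": "total", "age_band": "50-64", "education_band": "5-12", "mean": 20, "sd": 6},
    {"instrument": "ToulousePieron", "subscore": "total", "age_band": "65-80", "education_band": "5-12", "mean": 16, "sd": 6},

    {"instrument": "ROCFT", "subscore": "recall_3min", "age_band": "50-64", "education_band": "5-12", "mean": 17, "sd": 6},
    {"instrument": "ROCFT", "subscore": "recall_3min", "age_band": "65-80", "education_band": "5-12", "mean": 14, "sd": 6},
    {"instrument": "ROCFT", "subscore": "copy", "age_band": "50-64", "education_band": "5-12", "mean": 30, "sd": 5},
    {"instrument": "ROCFT", "subscore": "copy", "age_band": "65-80", "education_band": "5-12", "mean": 27, "sd": 6}
  ]
}
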