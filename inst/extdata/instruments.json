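{
  "description": "Registry of NPA instruments and their bounded subscores. higher_is_better = false marks reverse-scored instruments (impairment/symptom scales where a higher raw score means worse functioning).",
  "subscores": [
    {"instrument": "MoCA", "subscore": "total", "min": 0, "max": 30, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "temporal_spatial_orientation", "min": 0, "max": 6, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "delayed_recall", "min": 0, "max": 5, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "digit_reverse", "min": 0, "max": 1, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "digit_direct", "min": 0, "max": 1, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "calculus", "min": 0, "max": 3, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "target_detection", "min": 0, "max": 1, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "phonemic_verbal_fluency", "min": 0, "max": 1, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "naming_repetition", "min": 0, "max": 5, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "attention", "min": 0, "max": 6, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "memory", "min": 0, "max": 11, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "executive", "min": 0, "max": 7, "higher_is_better": true},
    {"instrument": "MoCA", "subscore": "language", "min": 0, "max": 6, "higher_is_better": true},

    {"instrument": "CDR", "subscore": "cognitive_cluster", "min": 0, "max": 18, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "orientation", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "immediate_memory", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "memory_delayed_recall", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "personal_care", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "home_hobbies", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "community_affairs", "min": 0, "max": 3, "higher_is_better": false},
    {"instrument": "CDR", "subscore": "judgment_problem_solving", "min": 0, "max": 3, "higher_is_better": false},

    {"instrument": "FCSRT", "subscore": "immediate_memory", "min": 0, "max": 48, "higher_is_better": true},
    {"instrument": "FCSRT", "subscore": "delayed_recall", "min": 0, "max": 16, "higher_is_better": true},

    {"instrument": "ROCFT", "subscore": "recall_3min", "min": 0, "max": 36, "higher_is_better": true},
    {"instrument": "ROCFT", "subscore": "copy", "min": 0, "max": 36, "higher_is_better": true},

    {"instrument": "WMS_III", "subscore": "visual_reproduction_immediate", "min": 0, "max": 104, "higher_is_better": true},
    {"instrument": "WMS_III", "subscore": "visual_reproduction_delayed", "min": 0, "max": 104, "higher_is_better": true},
    {"instrument": "WMS_III", "subscore": "visual_reproduction_recognition", "min": 0, "max": 7, "higher_is_better": true},
    {"instrument": "WMS_III", "subscore": "visual_reproduction_total", "min": 0, "max": 104, "higher_is_better": true},

    {"instrument": "WAIS_III", "subscore": "digit_symbol_coding", "min": 0, "max": 133, "higher_is_better": true},
    {"instrument": "WAIS_III", "subscore": "symbol_search", "min": 0, "max": 60, "higher_is_better": true},
    {"instrument": "WAIS_III", "subscore": "vocabulary", "min": 0, "max": 66, "higher_is_better": true},

    {"instrument": "VerbalFluency", "subscore": "phonemic_semantic", "min": 0, "max": 84, "higher_is_better": true},
    {"instrument": "VerbalFluency", "subscore": "phonemic", "min": 0, "max": 57, "higher_is_better": true},
    {"instrument": "VerbalFluency", "subscore": "semantic", "min": 0, "max": 27, "higher_is_better": true},

    {"instrument": "ToulousePieron", "subscore": "total", "min": 0, "max": 37.5, "higher_is_better": true},

    {"instrument": "IAFAI", "subscore": "basic_adl", "min": 0, "max": 100, "higher_is_better": false},
    {"instrument": "IAFAI", "subscore": "instrumental_familiar", "min": 0, "max": 100, "higher_is_better": false},
    {"instrument": "IAFAI", "subscore": "instrumental_advanced", "min": 0, "max": 100, "higher_is_better": false},

    {"instrument": "PRECiS", "subscore": "total", "min": 0, "max": 100, "higher_is_better": false},
    {"instrument": "GDS30", "subscore": "total", "min": 0, "max": 30, "higher_is_better": false},
    {"instrument": "BDI_II", "subscore": "total", "min": 0, "max": 63, "higher_is_better": false}
  ]
}
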