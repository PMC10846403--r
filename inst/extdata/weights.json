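{
  "description": "Expert consensus weight table mapping NPA instrument subscores to cognitive domains/subdomains. raw_pct is the non-normalized instrument weight; printed_pct is the published renormalized within-domain percentage.",
  "entries": [
    {"domain": "general_cognition", "instrument": "MoCA", "subscore": "total", "raw_pct": 100, "printed_pct": 50},
    {"domain": "general_cognition", "instrument": "CDR", "subscore": "cognitive_cluster", "raw_pct": 100, "printed_pct": 50},

    {"domain": "orientation", "instrument": "CDR", "subscore": "orientation", "raw_pct": 33.33, "printed_pct": 72.73},
    {"domain": "orientation", "instrument": "MoCA", "subscore": "temporal_spatial_orientation", "raw_pct": 12.5, "printed_pct": 27.27},

    {"domain": "memory.immediate_verbal", "instrument": "FCSRT", "subscore": "immediate_memory", "raw_pct": 100, "printed_pct": 68.57},
    {"domain": "memory.immediate_verbal", "instrument": "CDR", "subscore": "immediate_memory", "raw_pct": 33.33, "printed_pct": 22.86},
    {"domain": "memory.immediate_verbal", "instrument": "MoCA", "subscore": "delayed_recall", "raw_pct": 12.5, "printed_pct": 8.57},

    {"domain": "memory.immediate_visual", "instrument": "ROCFT", "subscore": "recall_3min", "raw_pct": 100, "printed_pct": 50},
    {"domain": "memory.immediate_visual", "instrument": "WMS_III", "subscore": "visual_reproduction_immediate", "raw_pct": 100, "printed_pct": 50},

    {"domain": "memory.delayed_verbal", "instrument": "FCSRT", "subscore": "delayed_recall", "raw_pct": 100, "printed_pct": 75},
    {"domain": "memory.delayed_verbal", "instrument": "CDR", "subscore": "memory_delayed_recall", "raw_pct": 33.33, "printed_pct": 25},

    {"domain": "memory.delayed_visual", "instrument": "WMS_III", "subscore": "visual_reproduction_delayed", "raw_pct": 100, "printed_pct": 50},
    {"domain": "memory.delayed_visual", "instrument": "WMS_III", "subscore": "visual_reproduction_recognition", "raw_pct": 100, "printed_pct": 50},

    {"domain": "executive.working_memory", "instrument": "WAIS_III", "subscore": "digit_symbol_coding", "raw_pct": 50, "printed_pct": 68.54},
    {"domain": "executive.working_memory", "instrument": "MoCA", "subscore": "digit_reverse", "raw_pct": 12.5, "printed_pct": 17.13},
    {"domain": "executive.working_memory", "instrument": "MoCA", "subscore": "calculus", "raw_pct": 6.25, "printed_pct": 8.57},
    {"domain": "executive.working_memory", "instrument": "MoCA", "subscore": "target_detection", "raw_pct": 4.2, "printed_pct": 5.76},

    {"domain": "executive.processing_speed", "instrument": "WAIS_III", "subscore": "symbol_search", "raw_pct": 50, "printed_pct": 36.36},
    {"domain": "executive.processing_speed", "instrument": "WAIS_III", "subscore": "digit_symbol_coding", "raw_pct": 50, "printed_pct": 36.36},
    {"domain": "executive.processing_speed", "instrument": "VerbalFluency", "subscore": "phonemic_semantic", "raw_pct": 33.33, "printed_pct": 24.23},
    {"domain": "executive.processing_speed", "instrument": "MoCA", "subscore": "phonemic_verbal_fluency", "raw_pct": 4.2, "printed_pct": 3.05},

    {"domain": "executive.verbal_fluency", "instrument": "VerbalFluency", "subscore": "phonemic_semantic", "raw_pct": 33.33, "printed_pct": 88.81},
    {"domain": "executive.verbal_fluency", "instrument": "MoCA", "subscore": "phonemic_verbal_fluency", "raw_pct": 4.2, "printed_pct": 11.19},

    {"domain": "executive.inhibition", "instrument": "VerbalFluency", "subscore": "phonemic_semantic", "raw_pct": 33.33, "printed_pct": 79.88},
    {"domain": "executive.inhibition", "instrument": "MoCA", "subscore": "target_detection", "raw_pct": 4.2, "printed_pct": 10.06},
    {"domain": "executive.inhibition", "instrument": "MoCA", "subscore": "phonemic_verbal_fluency", "raw_pct": 4.2, "printed_pct": 10.06},

    {"domain": "executive.visuoconstructive", "instrument": "ROCFT", "subscore": "copy", "raw_pct": 100, "printed_pct": 50},
    {"domain": "executive.visuoconstructive", "instrument": "WMS_III", "subscore": "visual_reproduction_total", "raw_pct": 100, "printed_pct": 50},

    {"domain": "language.comprehension", "instrument": "WAIS_III", "subscore": "vocabulary", "raw_pct": 50, "printed_pct": 100},
    {"domain": "language.expression", "instrument": "MoCA", "subscore": "naming_repetition", "raw_pct": 12.5, "printed_pct": 100},

    {"domain": "attention.divided", "instrument": "WAIS_III", "subscore": "symbol_search", "raw_pct": 50, "printed_pct": 100},

    {"domain": "attention.sustained", "instrument": "ToulousePieron", "subscore": "total", "raw_pct": 100, "printed_pct": 81.33},
    {"domain": "attention.sustained", "instrument": "MoCA", "subscore": "target_detection", "raw_pct": 4.2, "printed_pct": 3.42},
    {"domain": "attention.sustained", "instrument": "MoCA", "subscore": "calculus", "raw_pct": 6.25, "printed_pct": 5.08},
    {"domain": "attention.sustained", "instrument": "MoCA", "subscore": "digit_direct", "raw_pct": 12.5, "printed_pct": 10.17},

    {"domain": "premorbid_intelligence", "instrument": "WAIS_III", "subscore": "vocabulary", "raw_pct": 50, "printed_pct": 100},

    {"domain": "functionality.basic_adl", "instrument": "IAFAI", "subscore": "basic_adl", "raw_pct": 100, "printed_pct": 50},
    {"domain": "functionality.basic_adl", "instrument": "CDR", "subscore": "personal_care", "raw_pct": 100, "printed_pct": 50},

    {"domain": "functionality.instrumental_familiar", "instrument": "IAFAI", "subscore": "instrumental_familiar", "raw_pct": 100, "printed_pct": 50},
    {"domain": "functionality.instrumental_familiar", "instrument": "CDR", "subscore": "home_hobbies", "raw_pct": 100, "printed_pct": 50},

    {"domain": "functionality.instrumental_advanced", "instrument": "IAFAI", "subscore": "instrumental_advanced", "raw_pct": 100, "printed_pct": 33.33},
    {"domain": "functionality.instrumental_advanced", "instrument": "CDR", "subscore": "community_affairs", "raw_pct": 100, "printed_pct": 33.33},
    {"domain": "functionality.instrumental_advanced", "instrument": "CDR", "subscore": "judgment_problem_solving", "raw_pct": 100, "printed_pct": 33.33},

    {"domain": "functionality.perceived_impact", "instrument": "PRECiS", "subscore": "total", "raw_pct": 100, "printed_pct": 100},

    {"domain": "depressive_symptomatology", "instrument": "GDS30", "subscore": "total", "raw_pct": 100, "printed_pct": 100}
  ]
}
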