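{
  "description": "Simplified profiling scheme: performance-based subscores are min-max normalized to 0-10 and averaged, first within subdomain, then across subdomains, to yield five macro-domain scores.",
  "scale": {"min": 0, "max": 10},
  "macro_domains": [
    {
      "name": "general_cognition",
      "subdomains": [
        {"name": "screening", "entries": [
          {"instrument": "MoCA", "subscore": "total", "min": 0, "max": 30}
        ]}
      ]
    },
    {
      "name": "memory",
      "subdomains": [
        {"name": "immediate_verbal", "entries": [
          {"instrument": "FCSRT", "subscore": "immediate_memory", "min": 0, "max": 48}
        ]},
        {"name": "immediate_visual", "entries": [
          {"instrument": "ROCFT", "subscore": "recall_3min", "min": 0, "max": 36}
        ]},
        {"name": "delayed_verbal", "entries": [
          {"instrument": "FCSRT", "subscore": "delayed_recall", "min": 0, "max": 16}
        ]}
      ]
    },
    {
      "name": "executive_functions",
      "subdomains": [
        {"name": "working_memory", "entries": [
          {"instrument": "WAIS_III", "subscore": "digit_symbol_coding", "min": 0, "max": 133}
        ]},
        {"name": "processing_speed", "entries": [
          {"instrument": "WAIS_III", "subscore": "symbol_search", "min": 0, "max": 60},
          {"instrument": "WAIS_III", "subscore": "digit_symbol_coding", "min": 0, "max": 133}
        ]},
        {"name": "verbal_initiative", "entries": [
          {"instrument": "VerbalFluency", "subscore": "phonemic", "min": 0, "max": 57},
          {"instrument": "VerbalFluency", "subscore": "semantic", "min": 0, "max": 27}
        ]},
        {"name": "inhibition", "entries": [
          {"instrument": "VerbalFluency", "subscore": "phonemic", "min": 0, "max": 57},
          {"instrument": "VerbalFluency", "subscore": "semantic", "min": 0, "max": 27}
        ]},
        {"name": "visuoconstructive", "entries": [
          {"instrument": "ROCFT", "subscore": "copy", "min": 0, "max": 36}
        ]}
      ]
    },
    {
      "name": "language",
      "subdomains": [
        {"name": "expression", "entries": [
          {"instrument": "VerbalFluency", "subscore": "phonemic", "min": 0, "max": 57},
          {"instrument": "VerbalFluency", "subscore": "semantic", "min": 0, "max": 27}
        ]},
        {"name": "comprehension", "entries": [
          {"instrument": "WAIS_III", "subscore": "vocabulary", "min": 0, "max": 66}
        ]}
      ]
    },
    {
      "name": "attention",
      "subdomains": [
        {"name": "divided", "entries": [
          {"instrument": "WAIS_III", "subscore": "symbol_search", "min": 0, "max": 60}
        ]},
        {"name": "sustained", "entries": [
          {"instrument": "ToulousePieron", "subscore": "total", "min": 0, "max": 37.5}
        ]}
      ]
    }
  ]
}
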