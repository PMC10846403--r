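{
  "description": "Repository of cognitive training task (CTT) models: cognitive-status coverage ranges (0-100), training weights over domains (sum to 1), ADL contexts, difficulty-parameter bounds, and nominal play duration in minutes.",
  "tasks": [
    {
      "id": "search_kitchen",
      "kind": "search",
      "contexts": ["kitchen", "supermarket"],
      "nominal_minutes": 11,
      "coverage": {
        "attention": [20, 80],
        "memory": [30, 85],
        "executive_functions": [25, 75]
      },
      "training_weights": {"attention": 0.5, "memory": 0.3, "executive_functions": 0.2},
      "parameters": {
        "targets": [1, 12],
        "elements_per_section": [5, 20],
        "sections": [1, 8]
      }
    },
    {
      "id": "organize_recipe",
      "kind": "organize",
      "contexts": ["kitchen"],
      "nominal_minutes": 11,
      "coverage": {
        "executive_functions": [15, 70],
        "memory": [20, 75]
      },
      "training_weights": {"executive_functions": 0.6, "memory": 0.4},
      "parameters": {
        "steps": [2, 12]
      }
    },
    {
      "id": "categorize_pantry",
      "kind": "categorize",
      "contexts": ["kitchen", "supermarket"],
      "nominal_minutes": 11,
      "coverage": {
        "executive_functions": [20, 80],
        "language": [25, 80],
        "attention": [20, 70]
      },
      "training_weights": {"executive_functions": 0.4, "language": 0.3, "attention": 0.3},
      "parameters": {
        "items": [2, 60],
        "containers": [2, 4]
      }
    },
    {
      "id": "pay_groceries",
      "kind": "pay",
      "contexts": ["supermarket", "finances"],
      "nominal_minutes": 11,
      "coverage": {
        "executive_functions": [25, 85],
        "attention": [30, 80]
      },
      "training_weights": {"executive_functions": 0.7, "attention": 0.3},
      "parameters": {
        "bill_items": [1, 10],
        "coin_denominations": [2, 8]
      }
    },
    {
      "id": "drive_errands",
      "kind": "drive",
      "contexts": ["transport"],
      "nominal_minutes": 11,
      "coverage": {
        "attention": [35, 90],
        "executive_functions": [30, 85]
      },
      "training_weights": {"attention": 0.6, "executive_functions": 0.4},
      "parameters": {
        "obstacles_per_minute": [2, 20],
        "pickups": [1, 12]
      }
    }
  ]
}
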