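{
  "version": "1.0",
  "observation_days": 1095,
  "preterm_cutoff_days": 259,
  "criteria": [
    {"id": "nicu_stay",            "tier": "major", "score": 3},
    {"id": "hospitalizations",     "tier": "major", "score": 3},
    {"id": "multiple_specialists", "tier": "minor", "score": 1},
    {"id": "er_visits",            "tier": "minor", "score": 1},
    {"id": "feeding_support",      "tier": "minor", "score": 2},
    {"id": "respiratory_support",  "tier": "minor", "score": 2},
    {"id": "imaging",              "tier": "minor", "score": 1},
    {"id": "genetic_tests",        "tier": "minor", "score": 1},
    {"id": "metabolic_tests",      "tier": "minor", "score": 1},
    {"id": "death",                "tier": "major", "score": 3},
    {"id": "developmental_delay",  "tier": "minor", "score": 1},
    {"id": "metabolic_icd",        "tier": "major", "score": 3},
    {"id": "heart_surgery",        "tier": "major", "score": 3}
  ],
  "thresholds": {
    "nicu_min_days": 4,
    "nicu_birth_window_days": 7,
    "hosp_min_hours": 48,
    "hosp_prolonged_days": 14,
    "hosp_min_count": {"full_term": 2, "pre_term": 3},
    "hosp_min_pma_days": 245,
    "specialist_types": {"full_term": 3, "pre_term": 4},
    "er_visits": {"full_term": 5, "pre_term": 7},
    "dd_min_occurrences": 2,
    "metabolic_min_encounters": 2,
    "resp_days_before_surgery": 1,
    "resp_days_after_surgery": 5
  }
}
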