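{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "screenPLL run summary",
  "description": "Per-strategy summary entries written by write_outputs(); the top level maps strategy name to an entry.",
  "type": "object",
  "items": {
    "type": "object",
    "properties": {
      "strategy": {"type": "string"},
      "n_women": {"type": "number"},
      "n_exam_ages": {"type": "number"},
      "peak_life_months": {"type": "number"},
      "peak_age_years": {"type": "number"},
      "value_at_age_30": {"type": "number"},
      "value_at_age_45": {"type": "number"},
      "value_at_age_65": {"type": "number"},
      "value_at_age_80": {"type": "number"},
      "n_bca_deaths": {"type": "number"},
      "n_screen_detections": {"type": "number"},
      "n_overdiagnosed": {"type": "number"},
      "mean_exams_per_woman": {"type": "number"}
    },
    "required": ["strategy", "n_women", "peak_life_months", "peak_age_years",
                 "n_bca_deaths", "n_screen_detections", "n_overdiagnosed",
                 "mean_exams_per_woman"]
  }
}
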