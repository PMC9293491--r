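{
  "description": "Two-arm study outcome tables and continuous-measure summaries, transcribed from the published report (43 patients per arm).",
  "data_note": "The report's overall sex counts (39 M / 47 F) disagree with its per-arm counts (24+19 M, 19+23 F = 44 M / 42 F); these tables follow the per-arm version and the discrepancy is left unresolved.",
  "outcomes": {
    "experimental": {
      "n_good": 39, "n_poor": 3, "n_died": 1,
      "n_complications": 4, "n_total": 43
    },
    "control": {
      "n_good": 32, "n_poor": 9, "n_died": 2,
      "n_complications": 13, "n_total": 43
    }
  },
  "summaries": {
    "operation_time_min": {
      "experimental": {"mean": 180.3, "sd": 29.2, "n": 43},
      "control": {"mean": 173.9, "sd": 30.3, "n": 43}
    },
    "blood_loss_ml": {
      "experimental": {"mean": 234.4, "sd": 86.4, "n": 43},
      "control": {"mean": 256.4, "sd": 64.7, "n": 43}
    },
    "hospital_stay_days": {
      "experimental": {"mean": 19.9, "sd": 3.5, "n": 43},
      "control": {"mean": 23.2, "sd": 3.0, "n": 43}
    }
  }
}
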