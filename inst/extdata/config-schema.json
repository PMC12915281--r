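{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "quadmap run configuration",
  "type": "object",
  "properties": {
    "mode": {"enum": ["simulate", "files"], "default": "simulate"},
    "seed": {"type": "integer", "default": 1},
    "stimulus_onset": {"type": "number", "default": 0,
      "description": "Drug-onset time in seconds; FRET frames at or before it form the baseline window unless baseline_window is given"},
    "baseline_window": {"type": "array", "items": {"type": "integer"},
      "description": "Explicit 1-based FRET frame indices of the baseline period"},
    "schedule": {
      "type": "object",
      "properties": {
        "fret_period": {"type": "number", "default": 10},
        "fret_exposure": {"type": "number", "default": 0.1},
        "burst_rate": {"type": "number", "default": 1000},
        "burst_duration": {"type": "number", "default": 2},
        "total_duration": {"type": "number", "default": 120},
        "burst_offset": {"type": "number", "default": 0.05}
      }
    },
    "geometry": {
      "type": "object",
      "description": "simulate mode only",
      "properties": {
        "rows": {"type": "integer", "default": 64},
        "cols": {"type": "integer", "default": 64},
        "preset": {"enum": ["ventricle_anterior", "atria_posterior"],
          "default": "ventricle_anterior"}
      }
    },
    "drug": {"enum": ["ne", "ach", "tyramine"], "default": "ne"},
    "paths": {
      "type": "object",
      "description": "files mode only; all TIFF stacks with JSON sidecars",
      "properties": {
        "cfp": {"type": "string"},
        "yfp": {"type": "string"},
        "mask": {"type": "string"},
        "vm": {"type": "array", "items": {"type": "string"}},
        "ca": {"type": "array", "items": {"type": "string"}}
      },
      "required": ["cfp", "yfp", "mask", "vm", "ca"]
    },
    "roi_file": {"type": "string",
      "description": "ROI JSON (0-based row/col pixel lists or polygons)"},
    "n_beats": {"type": "integer", "default": 10},
    "polarity": {
      "type": "object",
      "properties": {"vm": {"enum": [-1, 1], "default": -1},
                     "ca": {"enum": [-1, 1], "default": 1}}
    },
    "yfp_offset": {"type": "number", "default": 0,
      "description": "files mode: camera offset used for the YFP floor (5x offset)"}
  }
}
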