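{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "oriscan result",
  "type": "object",
  "required": ["tool", "version", "seed", "config_hash", "input", "mode",
               "records", "n_candidates", "predictions"],
  "properties": {
    "tool": {"type": "string", "const": "oriscan"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "input": {"type": "string"},
    "mode": {"enum": ["complete", "draft"]},
    "records": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "length", "topology", "n_features"],
        "properties": {
          "id": {"type": "string"},
          "length": {"type": "integer"},
          "topology": {"enum": ["circular", "linear"]},
          "n_features": {"type": "integer"}
        }
      }
    },
    "n_candidates": {"type": "integer"},
    "predictions": {
      "type": "array",
      "description": "ranked oriC predictions; coordinates 1-based inclusive",
      "items": {
        "type": "object",
        "required": ["record_id", "start", "end", "length", "s_dist",
                     "s_gene", "s_box", "total"],
        "properties": {
          "record_id": {"type": "string"},
          "start": {"type": "integer", "minimum": 1},
          "end": {"type": "integer", "minimum": 1},
          "wraps_origin": {"type": "boolean"},
          "length": {"type": "integer"},
          "s_dist": {"type": "number", "minimum": 0, "maximum": 1},
          "s_gene": {"type": "number", "minimum": 0, "maximum": 1},
          "s_box": {"type": "number", "minimum": 0, "maximum": 1},
          "total": {"type": "number", "minimum": 0, "maximum": 3},
          "n_dnaa_boxes": {"type": "integer"},
          "n_dnaa_trios": {"type": "integer"},
          "n_gatc": {"type": "integer"},
          "elements": {"type": "array"}
        }
      }
    },
    "terminus": {
      "type": "object",
      "required": ["position", "method"],
      "properties": {
        "position": {"type": "integer", "minimum": 1},
        "method": {"enum": ["dif", "gc_max"]}
      }
    },
    "strand_bias": {"type": "object"},
    "warning": {"type": "string"}
  }
}
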