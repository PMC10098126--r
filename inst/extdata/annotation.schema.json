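{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "DDHdx annotation file",
  "type": "object",
  "required": ["landmarks"],
  "properties": {
    "schema_version": {"type": "string"},
    "image": {"type": "string", "description": "path of the radiograph"},
    "patient": {
      "type": "object",
      "required": ["nationality", "sex", "age_years"],
      "properties": {
        "nationality": {"enum": ["chinese", "other"]},
        "sex": {"enum": ["female", "male"]},
        "age_years": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "landmarks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "side", "x", "y"],
        "properties": {
          "label": {"enum": ["lateral_acetabular_edge", "triradiate_top",
                             "metaphysis_inner", "metaphysis_outer"]},
          "side": {"enum": ["left", "right"]},
          "x": {"type": "number", "minimum": 0},
          "y": {"type": "number", "minimum": 0}
        }
      },
      "description": "at most one entry per (label, side); 0-based pixel coordinates, x rightward, y downward"
    }
  }
}
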