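{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fastqmeta results document",
  "type": "object",
  "required": ["library_stats", "library_source", "library_type",
               "read_orientation", "read_layout"],
  "additionalProperties": false,
  "definitions": {
    "read_length": {
      "type": "object",
      "required": ["min", "max", "mean", "median", "mode"],
      "properties": {
        "min": {"type": "integer", "minimum": 1},
        "max": {"type": "integer", "minimum": 1},
        "mean": {"type": "number"},
        "median": {"type": "number"},
        "mode": {"type": "integer", "minimum": 1}
      }
    },
    "source": {
      "type": "object",
      "required": ["short_name", "taxon_id"],
      "properties": {
        "short_name": {"type": ["string", "null"]},
        "taxon_id": {"type": ["integer", "null"], "minimum": 1}
      }
    },
    "layout": {
      "type": "object",
      "required": ["adapt_3", "polya_fraction"],
      "properties": {
        "adapt_3": {"type": ["string", "null"], "pattern": "^[ACGT]{12}$"},
        "polya_fraction": {"type": ["number", "null"], "minimum": 0, "maximum": 1}
      }
    }
  },
  "properties": {
    "library_stats": {
      "type": "object",
      "required": ["file_1"],
      "properties": {
        "file_1": {"type": "object", "properties": {"read_length": {"$ref": "#/definitions/read_length"}}},
        "file_2": {"type": "object", "properties": {"read_length": {"$ref": "#/definitions/read_length"}}}
      }
    },
    "library_source": {
      "type": "object",
      "required": ["file_1"],
      "properties": {
        "file_1": {"$ref": "#/definitions/source"},
        "file_2": {"$ref": "#/definitions/source"}
      }
    },
    "library_type": {
      "type": "object",
      "required": ["file_1", "relationship"],
      "properties": {
        "file_1": {"type": ["string", "null"],
                   "enum": ["single", "first_mate", "second_mate", "mixed_mates", "undetermined", null]},
        "file_2": {"type": ["string", "null"],
                   "enum": ["single", "first_mate", "second_mate", "mixed_mates", "undetermined", null]},
        "relationship": {"type": ["string", "null"],
                         "enum": ["split_mates", "not_mates", "undetermined", null]}
      }
    },
    "read_orientation": {
      "type": "object",
      "required": ["file_1", "relationship"],
      "properties": {
        "file_1": {"type": ["string", "null"], "enum": ["SF", "SR", "U", "undetermined", null]},
        "file_2": {"type": ["string", "null"], "enum": ["SF", "SR", "U", "undetermined", null]},
        "relationship": {"type": ["string", "null"], "enum": ["ISF", "ISR", "IU", "undetermined", null]}
      }
    },
    "read_layout": {
      "type": "object",
      "required": ["file_1"],
      "properties": {
        "file_1": {"$ref": "#/definitions/layout"},
        "file_2": {"$ref": "#/definitions/layout"}
      }
    }
  }
}
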