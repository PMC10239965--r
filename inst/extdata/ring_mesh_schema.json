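{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ribmorph neutral ring-mesh format",
  "description": "Shell-element rib cortical bone geometry as ordered circumferential node rings with shell thickness. Rings are ordered along the rib (vertebral end first); nodes are ordered around the circumference. All coordinates and thicknesses are millimetres. A scalar thickness is broadcast to every node of the ring.",
  "type": "object",
  "required": ["model", "sex", "rib", "rings"],
  "properties": {
    "model": { "type": "string" },
    "sex": { "enum": ["M", "F"] },
    "rib": { "type": "integer", "minimum": 2, "maximum": 11 },
    "rings": {
      "type": "array",
      "minItems": 2,
      "items": {
        "type": "object",
        "required": ["nodes", "thickness"],
        "properties": {
          "nodes": {
            "type": "array",
            "minItems": 3,
            "items": {
              "type": "array",
              "items": { "type": "number" },
              "minItems": 3,
              "maxItems": 3
            }
          },
          "thickness": {
            "oneOf": [
              { "type": "number", "exclusiveMinimum": 0 },
              { "type": "array", "items": { "type": "number", "exclusiveMinimum": 0 } }
            ]
          }
        }
      }
    }
  }
}
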