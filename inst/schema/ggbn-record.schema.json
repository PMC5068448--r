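{
  "$id": "gelquant/ggbn-record",
  "title": "GGBN gel image quality record",
  "type": "object",
  "required": ["DNAThreshold", "percentAboveThreshold", "ladderName",
               "imageID", "laneLabel", "method", "warnings"],
  "properties": {
    "DNAThreshold": {"type": "number", "minimum": 1},
    "percentAboveThreshold": {"type": ["number", "null"],
                              "minimum": 0, "maximum": 100},
    "ladderName": {"type": "string"},
    "imageID": {"type": "string"},
    "laneLabel": {"type": "string"},
    "areaAbove": {"type": "number", "minimum": 0},
    "areaBelow": {"type": "number", "minimum": 0},
    "genomicQuality": {"type": ["boolean", "null"]},
    "method": {"type": "object"},
    "warnings": {"type": ["array", "null"]}
  }
}
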