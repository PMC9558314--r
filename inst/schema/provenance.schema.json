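{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gridtopo analysis provenance",
  "type": "object",
  "required": ["software", "version", "r_version", "timestamp", "parameters"],
  "properties": {
    "software": {"type": "string"},
    "version": {"type": "string"},
    "r_version": {"type": "string"},
    "timestamp": {"type": "string"},
    "parameters": {
      "type": "object",
      "description": "All user-facing knobs of the run: input path, graph construction and jitter seed, ascent method, tolerances, integrand, generator seeds."
    }
  }
}
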