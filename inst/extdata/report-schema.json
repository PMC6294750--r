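{
  "required_top_level": ["package", "version", "seed", "stages", "status"],
  "stages": ["data", "tensor", "fact", "gibbs", "quant", "cluster"],
  "stage_required": ["status"],
  "status_values": ["ok", "failed", "skipped"]
}
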