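{
  "system": {"complex": "1OTf", "radical": "PM"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 20.0, "product_energy": 4.0, "reversible": true}
  ]
}
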