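{
  "system": {"complex": "1Br", "radical": "PM"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 11.0, "product_energy": -25.0, "reversible": false},
    {"name": "Br", "ligand": "Br", "position": "equatorial", "ts_energy": 2.0, "product_energy": -27.0, "reversible": false}
  ]
}
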