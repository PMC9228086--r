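{
  "system": {"complex": "1Br", "radical": "PP"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 12.5, "product_energy": -25.0, "reversible": false},
    {"name": "Br", "ligand": "Br", "position": "equatorial", "ts_energy": 4.4, "product_energy": -26.0, "reversible": false}
  ]
}
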