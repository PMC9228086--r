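{
  "system": {"complex": "1Br", "radical": "trityl"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 23.6, "product_energy": -20.0, "reversible": false},
    {"name": "Br", "ligand": "Br", "position": "equatorial", "ts_energy": 13.2, "product_energy": 6.0, "reversible": true}
  ]
}
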