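{
  "system": {"complex": "1Cl", "radical": "PP"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 8.1, "product_energy": -25.0, "reversible": false},
    {"name": "Cl", "ligand": "Cl", "position": "equatorial", "ts_energy": 5.1, "product_energy": -26.0, "reversible": false}
  ]
}
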