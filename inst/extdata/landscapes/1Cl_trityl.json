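{
  "system": {"complex": "1Cl", "radical": "trityl"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "distal", "ts_energy": 23.2, "product_energy": -20.0, "reversible": false},
    {"name": "Cl", "ligand": "Cl", "position": "equatorial", "ts_energy": 24.6, "product_energy": 5.5, "reversible": true}
  ]
}
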