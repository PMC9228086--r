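{
  "system": {"complex": "2OH", "radical": "trityl"},
  "reactant_offset": 7.8,
  "channels": [
    {"name": "OH", "ligand": "OH", "position": "equatorial", "ts_energy": 11.9, "product_energy": -20.0, "reversible": false},
    {"name": "Cl", "ligand": "Cl", "position": "distal", "ts_energy": 19.8, "product_energy": 5.5, "reversible": true}
  ]
}
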