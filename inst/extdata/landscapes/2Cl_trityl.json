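{
  "system": {"complex": "2Cl", "radical": "trityl"},
  "reactant_offset": 0.0,
  "channels": [
    {"name": "Cl_eq", "ligand": "Cl", "position": "equatorial", "ts_energy": 7.4, "product_energy": -23.0, "reversible": false},
    {"name": "Cl_dist", "ligand": "Cl", "position": "distal", "ts_energy": 17.6, "product_energy": -23.0, "reversible": false}
  ]
}
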