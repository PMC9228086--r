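{
  "complex": "1Cl",
  "pi_gap": 99.2,
  "sigma_gap": 88.8,
  "exc_pi_to_pixy": null,
  "exc_sigma_to_pixy": null,
  "calibrated": false,
  "source": {"tag": "reported", "note": "alpha-orbital pair splittings of the 5Re_1Cl reactant complex; the equatorial sigma three-electron bond is the weaker pair"}
}
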