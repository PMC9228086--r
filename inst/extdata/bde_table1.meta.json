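{
  "file": "bde_table1.tsv",
  "units": "kcal/mol",
  "source": {
    "cx_bde": {"tag": "reported", "note": "UB3LYP/6-311+G* homolytic bond dissociation energies of the C-X bonds in the product complexes (published thermochemistry table)"},
    "metal_bde": {"tag": "reported", "note": "diabatic Fe-OH and Fe-Cl bond energies of the 5Re_1Cl reactant complex, frozen-fragment single points"}
  }
}
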