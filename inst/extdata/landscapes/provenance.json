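{
  "units": "kcal/mol, relative to the reactant complex of each landscape",
  "tags": {
    "reported": "value taken from the published DFT stationary-point energetics (UB3LYP/BS2//UB3LYP/BS1, DeltaE+ZPE, solvent included)",
    "synthetic": "stand-in constructed by this package where no value is printed; chosen to encode the qualitatively stated channel structure"
  },
  "files": {
    "1Cl_trityl.json": {
      "OH.ts_energy": "reported", "OH.product_energy": "reported (hydroxylation 'highly exothermic by ~20')",
      "Cl.ts_energy": "reported", "Cl.product_energy": "reported (+5.5 above reactants)"
    },
    "1Br_trityl.json": {
      "OH.ts_energy": "reported", "OH.product_energy": "reported (~-20)",
      "Br.ts_energy": "reported", "Br.product_energy": "reported (+6.0 above reactants)"
    },
    "1F_trityl.json": {
      "OH.ts_energy": "reported", "OH.product_energy": "synthetic (set equal to the other hydroxylation channels, ~-20)",
      "F.ts_energy": "reported", "F.product_energy": "reported qualitatively ('exothermic by almost 20'), encoded as -19.0"
    },
    "2Cl_trityl.json": {
      "Cl_eq.ts_energy": "reported (7.4)", "Cl_dist.ts_energy": "reported (17.6)",
      "Cl_eq.product_energy": "synthetic (efficient, effectively irreversible halogen transfer observed experimentally, 80% yield)",
      "Cl_dist.product_energy": "synthetic (same product complex as the equatorial channel)"
    },
    "2OH_trityl.json": {
      "reactant_offset": "reported (Re_2OH less stable than Re_1Cl by 7.8)",
      "OH.ts_energy": "reported (11.9)", "Cl.ts_energy": "reported (19.8)",
      "OH.product_energy": "synthetic (hydroxylation exothermicity carried over from the parent complex)",
      "Cl.product_energy": "synthetic (endergonic halide product as in the parent complex)"
    },
    "1Cl_PP.json": {
      "OH.ts_energy": "reported (8.1)", "Cl.ts_energy": "reported (5.1)",
      "OH.product_energy": "synthetic", "Cl.product_energy": "synthetic (halogen transfer to 2-degree radicals stated exothermic with unlikely reverse reactions)"
    },
    "1Br_PP.json": {
      "OH.ts_energy": "reported (12.5)", "Br.ts_energy": "reported (4.4)",
      "OH.product_energy": "synthetic", "Br.product_energy": "synthetic"
    },
    "1Cl_PM_synthetic.json": "fully synthetic stand-in: transition-state and product energies follow the reported PP pattern (halide TS below hydroxyl TS, both channels strongly exergonic/irreversible)",
    "1Br_PM_synthetic.json": "fully synthetic stand-in, as 1Cl_PM_synthetic.json",
    "1OTf_PM_synthetic.json": "fully synthetic model of the triflate null result: a single endergonic, reversible hydroxyl channel and no productive rebound partner"
  }
}
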