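{
  "vb_barriers": {
    "1Cl.trityl.X_transfer": 25.4,
    "1Cl.trityl.OH_transfer": 23.5,
    "1Cl.PP.X_transfer": 16.3,
    "1Cl.PP.OH_transfer": 15.1,
    "1Cl.PM.X_transfer": 7.9,
    "1Cl.PM.OH_transfer": 9.4
  },
  "vb_barrier_tolerance": 0.5,
  "driving_forces": {"Cl": 17.6, "OH": 15.8},
  "selectivity_calls": {
    "1Cl_trityl": "hydroxylation",
    "1Br_trityl": "hydroxylation",
    "1F_trityl": "halogenation",
    "2Cl_trityl": "halogenation",
    "2OH_trityl": "hydroxylation",
    "1Cl_PP": "halogenation",
    "1Br_PP": "halogenation",
    "1Cl_PM": "halogenation",
    "1Br_PM": "halogenation",
    "1OTf_PM": "no_productive_reaction"
  },
  "bep_flags": {"1Br_trityl": "inverted", "1F_trityl": "inverted"},
  "perturbation_lowest": {"full": "OH", "no_sterics": "X", "no_hbonds": "X", "neither": "OH"},
  "perturbation_gaps": {"full": 1.4, "no_sterics": 4.2, "no_hbonds": 6.9, "neither": 2.8},
  "perturbation_bep": {"neither": "compliant"},
  "position_2Cl": {"preferred": "equatorial", "gap": 10.2}
}
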