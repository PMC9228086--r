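# Second-coordination-sphere perturbation series for 1Cl + trityl:
# OH and Cl rebound barriers and reaction energies for the full scaffold and
# for truncations with sterics (no_sterics), hydrogen bonding (no_hbonds) or
# both (neither) removed. kcal/mol relative to each variant's reactant
# complex. Reported values: the full-system barriers (23.2/24.6) and the
# winning-channel gaps (Cl lowest by 4.2 for no_sterics and 6.9 for
# no_hbonds; OH lowest by 2.8 for neither). Absolute truncated barriers and
# all reaction energies are synthetic stand-ins honouring those gaps and the
# stated trends (halide product endergonic, hydroxylation ~-20, in every
# variant).
variant	channel	barrier_kcal_mol	reaction_energy_kcal_mol
full	OH	23.2	-20.0
full	X	24.6	5.5
no_sterics	OH	16.2	-20.0
no_sterics	X	12.0	5.5
no_hbonds	OH	18.4	-20.0
no_hbonds	X	11.5	5.5
neither	OH	9.0	-20.0
neither	X	11.8	5.5
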