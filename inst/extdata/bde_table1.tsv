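# Homolytic C-X bond dissociation energies (DeltaE + ZPE, solvent included)
# and diabatic Fe-L bond energies for the 5Re_1Cl reactant complex. kcal/mol.
radical	ligand	bde_kcal_mol
trityl	F	83.2
trityl	Cl	46.2
trityl	Br	34.3
trityl	OH	59.2
trityl	OTf	47.0
PP	F	91.3
PP	Cl	55.4
PP	Br	43.6
PP	OH	67.6
PP	OTf	56.8
PM	F	95.8
PM	Cl	63.7
PM	Br	52.8
PM	OH	73.3
PM	OTf	68.1

complex	ligand	bde_kcal_mol
1Cl	OH	75.0
1Cl	Cl	63.8
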