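# Default counterion list for parent extraction (name<TAB>SMILES<TAB>tier).
# Fragments are matched by InChI after per-fragment neutralization, so the
# charge state written here is irrelevant. Inorganic counterions are
# stripped before organic salt formers, so that e.g. sodium acetate resolves
# to acetic acid rather than to an empty molecule.
sodium	[Na+]	inorganic
potassium	[K+]	inorganic
lithium	[Li+]	inorganic
calcium	[Ca+2]	inorganic
magnesium	[Mg+2]	inorganic
zinc	[Zn+2]	inorganic
ammonium	[NH4+]	inorganic
chloride	Cl	inorganic
bromide	Br	inorganic
iodide	I	inorganic
fluoride	F	inorganic
hydroxide	[OH-]	inorganic
nitrate	O[N+]([O-])=O	inorganic
sulfate	OS(O)(=O)=O	inorganic
phosphate	OP(O)(O)=O	inorganic
acetate	CC(O)=O	organic
formate	OC=O	organic
oxalate	OC(=O)C(O)=O	organic
maleate	OC(=O)/C=C\C(O)=O	organic
fumarate	OC(=O)/C=C/C(O)=O	organic
tartrate	OC(C(O)C(O)=O)C(O)=O	organic
citrate	OC(=O)CC(O)(CC(O)=O)C(O)=O	organic
mesylate	CS(O)(=O)=O	organic
besylate	OS(=O)(=O)c1ccccc1	organic
tosylate	Cc1ccc(cc1)S(O)(=O)=O	organic
benzoate	OC(=O)c1ccccc1	organic
trifluoroacetate	OC(=O)C(F)(F)F	organic
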