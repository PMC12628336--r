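# Default solvent list for parent extraction (name<TAB>SMILES).
water	O
ethanol	CCO
methanol	CO
isopropanol	CC(C)O
dmso	CS(C)=O
acetone	CC(C)=O
acetonitrile	CC#N
dmf	CN(C)C=O
dichloromethane	ClCCl
chloroform	ClC(Cl)Cl
diethyl_ether	CCOCC
ethyl_acetate	CCOC(C)=O
thf	C1CCOC1
dioxane	C1COCCO1
toluene	Cc1ccccc1
hexane	CCCCCC
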