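# Compact functional-group SMARTS catalogue matching the synthetic
# generator's substituent vocabulary (name<TAB>SMARTS). For real analyses
# point read_fg_catalogue() at a full classification list, e.g. the
# ~300-entry functional-group file distributed with Open Babel
# (default_fg_catalogue_path()).
halogen	[F,Cl,Br,I]
nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
arom_amine	[NX3H2][c]
carboxylic_acid	[CX3](=O)[OX2H1]
ester	[CX3](=O)[OX2H0][#6]
methyl	[CX4H3][c]
aryl_ether	[OX2H0]([CX4H3])[c]
phenol	[OX2H][c]
# groups below are deliberately absent from the generator vocabulary; they
# exercise catalogue filtering (zero matches -> dropped)
sulfonamide	[SX4](=O)(=O)[NX3]
aldehyde	[CX3H1](=O)[#6]
nitrile	[NX1]#[CX2]
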