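# Target manifest: benchmark drugs with their complexity levels.
# The study-specific hidden target molecules are supplied by the user as a
# CSV in this same schema (id,smiles,complexity_level).
id,smiles,complexity_level
albuterol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1,L1
celecoxib,Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1,L2
thiothixene,CN(C)S(=O)(=O)c1ccc2c(c1)C(=CCCN1CCN(C)CC1)c1ccccc1S2,L3
aripiprazole,O=C1CCc2ccc(OCCCCN3CCN(c4cccc(Cl)c4Cl)CC3)cc2N1,L4
troglitazone,Cc1c(C)c2c(c(C)c1O)CCC(C)(COc1ccc(CC3SC(=O)NC3=O)cc1)O2,L5
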