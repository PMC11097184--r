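smiles	name
CC(N)Cc1ccccc1F	mol1_standin
CC(=O)Nc1ccc(Cl)c(Cl)c1Cl	mol2_standin
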