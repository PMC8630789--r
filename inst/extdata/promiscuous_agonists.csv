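compound,smiles,receptors
quinine,COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1,TAS2R4;TAS2R7;TAS2R10;TAS2R14;TAS2R31;TAS2R39;TAS2R40;TAS2R43;TAS2R46
amarogentin,C=CC1C2CCOC(=O)C2=COC1OC1OC(CO)C(O)C(O)C1OC(=O)c1cc(O)cc(O)c1-c1cccc(O)c1,TAS2R1;TAS2R4;TAS2R10;TAS2R30;TAS2R39;TAS2R43;TAS2R46
EGCG,Oc1cc(O)c2c(c1)OC(c1cc(O)c(O)c(O)c1)C(OC(=O)c1cc(O)c(O)c(O)c1)C2,TAS2R4;TAS2R5;TAS2R14;TAS2R30;TAS2R39;TAS2R43
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,TAS2R5;TAS2R9;TAS2R14;TAS2R43;TAS2R46
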