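receptor,n_compounds,n_unique_scaffolds,median_mw
TAS2R1,25,20,354
TAS2R4,14,34,586
TAS2R5,9,52,578
TAS2R7,10,26,535
TAS2R8,2,2,160
TAS2R10,12,20,410
TAS2R14,78,53,295
TAS2R16,8,6,318
TAS2R20,1,1,204
TAS2R30,4,14,477
TAS2R31,2,3,271
TAS2R38,5,6,163
TAS2R39,47,66,286
TAS2R40,8,8,354
TAS2R43,8,19,261
TAS2R46,20,31,335
TAS2R50,1,9,586
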