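complex_id,species,subunit_id
CPX_PROTEASOME_CORE,human,hsPSA1
CPX_PROTEASOME_CORE,human,hsPSA2
CPX_PROTEASOME_CORE,human,hsPSA3
CPX_PROTEASOME_CORE,human,hsPSA4
CPX_PROTEASOME_CORE,mouse,mmPsa1
CPX_PROTEASOME_CORE,mouse,mmPsa2
CPX_PROTEASOME_CORE,mouse,mmPsa3
CPX_PROTEASOME_CORE,mouse,mmPsa4
CPX_COATOMER,human,hsCOPA
CPX_COATOMER,human,hsCOPB
CPX_COATOMER,human,hsCOPG
CPX_VATPASE_V1,human,hsATP6V1A
CPX_VATPASE_V1,human,hsATP6V1B
CPX_VATPASE_V1,human,hsATP6V1C
CPX_VATPASE_V1,human,hsATP6V1D
CPX_VATPASE_V1,human,hsATP6V1E
CPX_EXOCYST,rat,rnEXOC1
CPX_EXOCYST,rat,rnEXOC2
CPX_EXOCYST,rat,rnEXOC3
CPX_EXOCYST,rat,rnEXOC4
CPX_LSM,human,hsLSM1
CPX_LSM,human,hsLSM2
CPX_LSM,human,hsLSM3
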