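source_id,target_id
hsPSA1,AT1G10001
hsPSA2,AT1G10002
hsPSA3,AT1G10003
hsPSA4,AT1G10004
mmPsa1,AT1G10001
mmPsa2,AT1G10002
mmPsa3,AT1G10003
mmPsa4,AT1G10004
hsCOPA,AT2G20001
hsCOPB,AT2G20002
hsATP6V1A,AT3G30001
hsATP6V1B,AT3G30002
hsATP6V1C,AT3G30003
hsATP6V1E,AT3G30005
rnEXOC1,AT4G40001
rnEXOC2,AT4G40002
hsLSM1,AT5G50001
hsLSM2,AT5G50002
hsLSM3,AT5G50003
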