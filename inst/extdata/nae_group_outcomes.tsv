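group	deaths	reports
MG_SPECTRUM	404	1319
IMMUNE_MYOPATHY	518	1845
AIE	99	489
GBS_SPECTRUM	75	389
ASEPTIC_MENINGITIS	9	251
MYELITIS	22	140
CIDP	1	51
NMOSD	3	26
CNS_VASCULITIS	2	22
MOGAD	1	6
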