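pt	group	nae
autoimmune encephalitis	AIE	TRUE
autoimmune encephalopathy	AIE	TRUE
encephalitis autoimmune	AIE	TRUE
immune-mediated encephalitis	AIE	TRUE
noninfective encephalitis	AIE	TRUE
guillain-barre syndrome	GBS_SPECTRUM	TRUE
miller fisher syndrome	GBS_SPECTRUM	TRUE
acute motor axonal neuropathy	GBS_SPECTRUM	TRUE
acute motor-sensory axonal neuropathy	GBS_SPECTRUM	TRUE
chronic inflammatory demyelinating polyradiculoneuropathy	CIDP	TRUE
immune-mediated myasthenia gravis	MG_SPECTRUM	TRUE
myasthenia gravis	MG_SPECTRUM	TRUE
myasthenia gravis crisis	MG_SPECTRUM	TRUE
myasthenic syndrome	MG_SPECTRUM	TRUE
ocular myasthenia	MG_SPECTRUM	TRUE
autoimmune myositis	IMMUNE_MYOPATHY	TRUE
dermatomyositis	IMMUNE_MYOPATHY	TRUE
immune-mediated myositis	IMMUNE_MYOPATHY	TRUE
myositis	IMMUNE_MYOPATHY	TRUE
necrotising myositis	IMMUNE_MYOPATHY	TRUE
necrotizing myositis	IMMUNE_MYOPATHY	TRUE
polymyositis	IMMUNE_MYOPATHY	TRUE
immune-mediated myelitis	MYELITIS	TRUE
myelitis	MYELITIS	TRUE
myelitis transverse	MYELITIS	TRUE
noninfectious myelitis	MYELITIS	TRUE
neuromyelitis optica spectrum disorder	NMOSD	TRUE
myelin oligodendrocyte glycoprotein antibody-associated disease	MOGAD	TRUE
acute disseminated encephalomyelitis	ADEM	TRUE
multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
primary progressive multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
progressive multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
progressive relapsing multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
relapsing multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
relapsing-remitting multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
secondary progressive multiple sclerosis	MULTIPLE_SCLEROSIS	TRUE
meningitis aseptic	ASEPTIC_MENINGITIS	TRUE
meningitis noninfective	ASEPTIC_MENINGITIS	TRUE
central nervous system vasculitis	CNS_VASCULITIS	TRUE
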