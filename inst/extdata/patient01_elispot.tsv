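method	rank	peptide	elispot
TruNeo	1	SEIISFKSL	true
TruNeo	2	AEVPENVFL	false
TruNeo	3	SEHGFGPSL	true
TruNeo	4	VEWLGRCIL	true
TruNeo	5	QQMGLLTRV	false
TruNeo	6	REEKIHDLA	true
TruNeo	7	LLCKMINLSK	false
TruNeo	8	SSEIISFKSL	true
TruNeo	9	STVPLDTLK	false
TruNeo	10	LEEEINRKM	false
MHCflurry	1	SLFWQTAMV	false
MHCflurry	2	LQFEYTFEI	false
MHCflurry	3	LLLCGVQAV	false
MHCflurry	4	ITAEIFMEK	false
MHCflurry	5	ATSPASASK	true
MHCflurry	6	MLICCCCTL	true
MHCflurry	7	ATHPIICFR	false
MHCflurry	8	STVPLDTLK	false
MHCflurry	9	LTVETLTKV	false
MHCflurry	10	HLEDFLLHI	false
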