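context6	proteases	source
PGKQGA	MMP2,MMP3,MMP8,MMP12,MMP13	MEROPS/CutDB
PQGFQG	MMP2,MMP3,MMP9,MMP12	MEROPS/CutDB
PAGERG	MMP2,MMP9,MMP13	MEROPS/CutDB
PSGFQG	MMP3,MMP8,MMP9,MMP12,MMP13	MEROPS/CutDB
PRGLPG	MMP8,MMP9,MMP12,MMP13	MEROPS/CutDB
PAGQPG	MMP8,MMP9,MMP12,ADAMTS4	MEROPS/CutDB
PPGKNG	MMP9,MMP13	MEROPS/CutDB
QPGSPG	MMP9,MMP13	MEROPS/CutDB
PRGERG	MMP9	MEROPS/CutDB
PAGQQG	MMP8,MMP9,MMP12,MMP13	MEROPS/CutDB
PGPSGK	ADAMTS5	MEROPS/CutDB
PGPAGP	ADAMTS5	MEROPS/CutDB
GPRGPP	CTSK,F2	CutDB
PPQEKA	CTSK	MEROPS/CutDB
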