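a	b	same
OCC	CCO	TRUE
OC(C)=O	CC(=O)O	TRUE
c1ccccc1	C1=CC=CC=C1	TRUE
CCO	CCN	FALSE
CC(=O)OCC	CCOC(C)=O	TRUE
C(F)(F)(F)C(=O)O	OC(=O)C(F)(F)F	TRUE
CCOCC	CCCOC	FALSE
Cc1ccccc1	c1ccccc1C	TRUE
CC(C)C	CCCC	FALSE
N[C@@H](C)C(=O)O	N[C@H](C)C(=O)O	FALSE
F/C=C/F	F/C=C\F	FALSE
CCN(C(=O)OC(C)(C)C)CC	CCN(CC)C(=O)OC(C)(C)C	TRUE
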