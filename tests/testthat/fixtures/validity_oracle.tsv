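smiles	valid
Cc1ccccc1Oc1ccc(CC)cc1	TRUE
Oc1ccc(Cl)cc1	TRUE
CCC(C)CNCCCC	TRUE
CCc1ccccc1NCCOCC	TRUE
CCCCN(C(=O)OC(C)(C)C)C	TRUE
COCC(=O)OCCC(C)C	TRUE
CCCCCC(=O)NCC(C)C	TRUE
CC(C)CNCc1ccccc1	TRUE
CC(C)(C)CNCCOCC	TRUE
NCc1ccccc1	TRUE
CC(C)COc1ccccc1	TRUE
NCCc1ccccc1	TRUE
CCCCCC(=O)NC	TRUE
CC(=O)NC	TRUE
CCCC(=O)OCCOCC	TRUE
CCOc1ccccc1	TRUE
FC(F)(F)C(=O)NCCC	TRUE
CC(C)(C)C(=O)OCc1ccccc1	TRUE
CCOCCOc1ccc(F)cc1	TRUE
CCCCCC(=O)OCCOCC	TRUE
CCc1ccccc1NCCC	TRUE
CC(C)C(=O)NCC	TRUE
CC(C)(C)CNCc1ccccc1	TRUE
CCNCC	TRUE
COCC(=O)OCCCCC	TRUE
CC(C)COc1ccc(C)cc1	TRUE
CC(C)(C)C(=O)NCC	TRUE
CCC(C)COc1ccc(C(C)(C)C)cc1	TRUE
CCC(C)CNCOC	TRUE
CCN(C(=O)OC(C)(C)C)Cc1ccccc1	TRUE
CCCC(=O)NCC(C)(C)C	TRUE
CCCCCC(=O)OCOC	TRUE
CCc1ccccc1N(C(=O)OC(C)(C)C)CC	TRUE
CC(C)C(=O)OC	TRUE
NCCC	TRUE
CCC(C)CN(C(=O)OC(C)(C)C)Cc1ccccc1	TRUE
CC(C)CNCC(C)(C)C	TRUE
CCCCC(=O)NCCCCC	TRUE
CC(C)c1ccccc1c1ccc(Cl)cc1	TRUE
CCBr	TRUE
CCOCCNCCc1ccccc1	TRUE
CCC(C)CN(C(=O)OC(C)(C)C)CC(C)C	TRUE
CCOCCOc1ccc(C)cc1	TRUE
c1ccccc1C(=O)OCCOCC	TRUE
c1ccccc1C(=O)OCCC(C)C	TRUE
COc1ccccc1c1ccccc1	TRUE
FC(F)(F)C(=O)OCC(C)(C)C	TRUE
Cc1ccccc1c1ccc(OC)cc1	TRUE
CCCCC(=O)NCCCC	TRUE
CCCCCC(=O)NCC	TRUE
CCC(=O)NCC(C)(C)C	TRUE
CCCCNCCOCC	TRUE
COCC(=O)OCCOCC	TRUE
CCCCCBr	TRUE
CC(=O)NCc1ccccc1	TRUE
c1ccccc1C(=O)OCc1ccccc1	TRUE
CCCCCOc1ccc(Cl)cc1	TRUE
CC(C)(C)COc1ccc(C)cc1	TRUE
CCCBr	TRUE
COCBr	TRUE
CCC(C)CNCCC(C)C	TRUE
FC(F)(F)C(=O)NCC(C)(C)C	TRUE
OC	TRUE
CCc1ccccc1N(C(=O)OC(C)(C)C)Cc1ccccc1	TRUE
FC(F)(F)C(=O)NCC	TRUE
CC(C)CNC	TRUE
CCC(=O)OC	TRUE
c1ccccc1C(=O)OCC	TRUE
CCC(C)CN(C(=O)OC(C)(C)C)CC	TRUE
CCCOc1ccc(OC)cc1	TRUE
CCCCN(C(=O)OC(C)(C)C)CCc1ccccc1	TRUE
CCC(C)COc1ccccc1	TRUE
Oc1ccc(C(C)(C)C)cc1	TRUE
CCCC(=O)NCCOCC	TRUE
CCCCCN(C(=O)OC(C)(C)C)CCC	TRUE
CCCCCOc1ccc(C)cc1	TRUE
CC(C)(C)CN(C(=O)OC(C)(C)C)CCC	TRUE
CC(C)(C)CNCC(C)(C)C	TRUE
CCCc1ccccc1c1ccc(C)cc1	TRUE
CCOCCBr	TRUE
CCc1ccccc1Oc1ccc(C)cc1	TRUE
COCN(C(=O)OC(C)(C)C)CC(C)(C)C	TRUE
CCCN(C(=O)OC(C)(C)C)CCC	TRUE
COCC(=O)NCCOCC	TRUE
CCc1ccccc1N(C(=O)OC(C)(C)C)COC	TRUE
c1ccccc1C(=O)O	TRUE
CCc1ccccc1Oc1ccc(OC)cc1	TRUE
CCCNCC(C)C	TRUE
CCc1ccccc1N(C(=O)OC(C)(C)C)CC(C)(C)C	TRUE
CCCC(=O)NCC	TRUE
CCCNCC(C)(C)C	TRUE
Oc1ccc(C)cc1	TRUE
CC(=O)OCCC	TRUE
CCCCNCCc1ccccc1	TRUE
CCCCNCC(C)(C)C	TRUE
c1ccccc1C(=O)OCCCCC	TRUE
CCCCOc1ccccc1	TRUE
CNCCCCC	TRUE
FC(F)(F)c1ccccc1c1ccc(C)cc1	TRUE
CN(C(=O)OC(C)(C)C)CCC(C)C	TRUE
Cc1cccccOc1ccc(CC)cc1	FALSE
Oc1ccc((Cl)cc1	FALSE
CCC((C)CNCCCC	FALSE
CCc1ccccc1NCCOCC(	FALSE
CCCCN(C((=O)OC(C)(C)C)C	FALSE
COCC(=O)OCCC((C)C	FALSE
CCCCCC(=O)NCC((C)C	FALSE
CC((C)CNCc1ccccc1	FALSE
CC(C)((C)CNCCOCC	FALSE
NCc1ccccc1(	FALSE
CC(C)COcccccc1	FALSE
NCCc1ccccc1(	FALSE
CCCCCC((=O)NC	FALSE
CC((=O)NC	FALSE
CCCC((=O)OCCOCC	FALSE
CCOc1ccccc(1	FALSE
FC(F)((F)C(=O)NCCC	FALSE
CC(C)((C)C(=O)OCc1ccccc1	FALSE
CCOCCOcccc(F)cc1	FALSE
CCCCCC((=O)OCCOCC	FALSE
CCcccccc1NCCC	FALSE
CC((C)C(=O)NCC	FALSE
CC(C)(C)CNCc1ccccc	FALSE
CC(NCC	FALSE
COCC((=O)OCCCCC	FALSE
CC(C)COc1ccc((C)cc1	FALSE
CC((C)(C)C(=O)NCC	FALSE
CCC(C)COc1ccc((C(C)(C)C)cc1	FALSE
CCC((C)CNCOC	FALSE
CCN(C((=O)OC(C)(C)C)Cc1ccccc1	FALSE
CCCC((=O)NCC(C)(C)C	FALSE
CCCCCC((=O)OCOC	FALSE
CCc1cccccN(C(=O)OC(C)(C)C)CC	FALSE
CC((C)C(=O)OC	FALSE
N(CCC	FALSE
CCC(C)CN(C((=O)OC(C)(C)C)Cc1ccccc1	FALSE
CC(C)CNCC(C)((C)C	FALSE
CCCCC((=O)NCCCCC	FALSE
CC(C)cccccc1c1ccc(Cl)cc1	FALSE
CCB(r	FALSE
CCOCCNCCcccccc1	FALSE
CCC(C)CN(C((=O)OC(C)(C)C)CC(C)C	FALSE
CCOCCOcccc(C)cc1	FALSE
c1ccccc1C((=O)OCCOCC	FALSE
cccccc1C(=O)OCCC(C)C	FALSE
CO(c1ccccc1c1ccccc1	FALSE
FC(F)(F)C(=O)OCC(C)((C)C	FALSE
Cc1ccccc1c1ccc((OC)cc1	FALSE
CCCCC((=O)NCCCC	FALSE
CCCCCC((=O)NCC	FALSE
CCC(=O)NCC((C)(C)C	FALSE
CCCCNCCOCC(	FALSE
COCC((=O)OCCOCC	FALSE
CCC(CCBr	FALSE
CC(=O)NCc1ccccc	FALSE
c1ccccc1C((=O)OCc1ccccc1	FALSE
CCCCCOc1ccc(Cl)cc	FALSE
CC((C)(C)COc1ccc(C)cc1	FALSE
C(CCBr	FALSE
COCBr(	FALSE
CCC((C)CNCCC(C)C	FALSE
FC(F)(F)C((=O)NCC(C)(C)C	FALSE
O(C	FALSE
CCc1ccccc1N((C(=O)OC(C)(C)C)Cc1ccccc1	FALSE
FC((F)(F)C(=O)NCC	FALSE
CC((C)CNC	FALSE
CCC((=O)OC	FALSE
c1ccccc1C((=O)OCC	FALSE
CCC((C)CN(C(=O)OC(C)(C)C)CC	FALSE
CCCOc1ccc((OC)cc1	FALSE
CCCCN(C(=O)OC(C)(C)C)CCc1ccccc	FALSE
CCC((C)COc1ccccc1	FALSE
Oc1ccc(C(C)(C)C)cc	FALSE
CCCC((=O)NCCOCC	FALSE
CCCCCN(C(=O)OC(C)((C)C)CCC	FALSE
CCCCCOc1ccc((C)cc1	FALSE
CC(C)(C)CN(C(=O)OC(C)((C)C)CCC	FALSE
CC(C)((C)CNCC(C)(C)C	FALSE
CCCc1ccccc1c1ccc(C)cc	FALSE
C(COCCBr	FALSE
CCcccccc1Oc1ccc(C)cc1	FALSE
COCN(C(=O)OC(C)(C)C)CC((C)(C)C	FALSE
CCCN((C(=O)OC(C)(C)C)CCC	FALSE
COCC((=O)NCCOCC	FALSE
CCcccccc1N(C(=O)OC(C)(C)C)COC	FALSE
c1ccccc1C((=O)O	FALSE
CCcccccc1Oc1ccc(OC)cc1	FALSE
CCCNCC((C)C	FALSE
CCcccccc1N(C(=O)OC(C)(C)C)CC(C)(C)C	FALSE
CCCC((=O)NCC	FALSE
CCCNCC((C)(C)C	FALSE
Oc1ccc((C)cc1	FALSE
CC((=O)OCCC	FALSE
CCCCNCCc1c(cccc1	FALSE
CCCCNCC(C)((C)C	FALSE
c1ccccc1C((=O)OCCCCC	FALSE
CCCCOc1ccccc	FALSE
CNCCCC(C	FALSE
FC(F)(F)c1cccccc1ccc(C)cc1	FALSE
CN(C(=O)OC(C)((C)C)CCC(C)C	FALSE
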