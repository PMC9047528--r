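smiles	ring_class
CCO	acyclic
CC(=O)OCC	acyclic
CCN	acyclic
FC(F)(F)C(=O)O	acyclic
CC(C)(C)OC(=O)NC	acyclic
CCOCC	acyclic
C	acyclic
CC(C)CC	acyclic
c1ccccc1	simple-ring
C1CCCCC1	simple-ring
c1ccncc1	simple-ring
Cc1ccc(C)cc1	simple-ring
C1CCNCC1	simple-ring
c1ccccc1CCc1ccccc1	simple-ring
O=C1CCCCC1	simple-ring
c1ccc2ccccc2c1	fused
C1CCC2CCCCC2C1	fused
C1Cc2ccccc2C1	fused
C1CCc2ccccc2C1	fused
c1ccc2cc3ccccc3cc2c1	fused
c1ccc2[nH]ccc2c1	fused
C1CCC2(CC1)CCCC2	spiro
C1CC2(C1)CCC2	spiro
C1CCC2(CC1)OCCO2	spiro
C1CC12CC2	spiro
C1CC2CCC1C2	bridged
C1CC2CCC1CC2	bridged
C1C2CC3CC1CC(C2)C3	bridged
C1CC2CC1C=C2	bridged
CN1C2CCC1CC(C2)O	bridged
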