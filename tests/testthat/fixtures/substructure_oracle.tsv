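smiles	boc	cf3	tbu
CC(C)(C)OC(=O)NC	TRUE	FALSE	TRUE
CC(C)(C)OC(=O)NCc1ccccc1	TRUE	FALSE	TRUE
OC(=O)C(F)(F)F	FALSE	TRUE	FALSE
FC(F)(F)c1ccccc1	FALSE	TRUE	FALSE
CC(C)(C)Oc1ccccc1	FALSE	FALSE	TRUE
CC(C)(C)C(=O)O	FALSE	FALSE	TRUE
CCO	FALSE	FALSE	FALSE
c1ccccc1	FALSE	FALSE	FALSE
CC(C)C	FALSE	FALSE	FALSE
CC(C)(C)OC(=O)OC(=O)OC(C)(C)C	FALSE	FALSE	TRUE
CCN(C(=O)OC(C)(C)C)CC	TRUE	FALSE	TRUE
CC(C)(C)c1ccc(C(F)(F)F)cc1	FALSE	TRUE	TRUE
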