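"smiles","atom","atomic_number","degree","num_hydrogens","implicit_valence","is_aromatic"
"C",1,6,0,4,4,0
"CC",1,6,1,3,3,0
"CC",2,6,1,3,3,0
"CCC",1,6,1,3,3,0
"CCC",2,6,2,2,2,0
"CCC",3,6,1,3,3,0
"CCCC",1,6,1,3,3,0
"CCCC",2,6,2,2,2,0
"CCCC",3,6,2,2,2,0
"CCCC",4,6,1,3,3,0
"CC(C)(C)C",1,6,1,3,3,0
"CC(C)(C)C",2,6,4,0,0,0
"CC(C)(C)C",3,6,1,3,3,0
"CC(C)(C)C",4,6,1,3,3,0
"CC(C)(C)C",5,6,1,3,3,0
"CCO",1,6,1,3,3,0
"CCO",2,6,2,2,2,0
"CCO",3,8,1,1,1,0
"CCCO",1,6,1,3,3,0
"CCCO",2,6,2,2,2,0
"CCCO",3,6,2,2,2,0
"CCCO",4,8,1,1,1,0
"CC(O)C",1,6,1,3,3,0
"CC(O)C",2,6,3,1,1,0
"CC(O)C",3,8,1,1,1,0
"CC(O)C",4,6,1,3,3,0
"CCOCC",1,6,1,3,3,0
"CCOCC",2,6,2,2,2,0
"CCOCC",3,8,2,0,0,0
"CCOCC",4,6,2,2,2,0
"CCOCC",5,6,1,3,3,0
"CC=O",1,6,1,3,3,0
"CC=O",2,6,2,1,1,0
"CC=O",3,8,1,0,0,0
"CCC=O",1,6,1,3,3,0
"CCC=O",2,6,2,2,2,0
"CCC=O",3,6,2,1,1,0
"CCC=O",4,8,1,0,0,0
"CC(=O)C",1,6,1,3,3,0
"CC(=O)C",2,6,3,0,0,0
"CC(=O)C",3,8,1,0,0,0
"CC(=O)C",4,6,1,3,3,0
"CCC(=O)C",1,6,1,3,3,0
"CCC(=O)C",2,6,2,2,2,0
"CCC(=O)C",3,6,3,0,0,0
"CCC(=O)C",4,8,1,0,0,0
"CCC(=O)C",5,6,1,3,3,0
"CC(=O)O",1,6,1,3,3,0
"CC(=O)O",2,6,3,0,0,0
"CC(=O)O",3,8,1,0,0,0
"CC(=O)O",4,8,1,1,1,0
"COC(=O)C",1,6,1,3,3,0
"COC(=O)C",2,8,2,0,0,0
"COC(=O)C",3,6,3,0,0,0
"COC(=O)C",4,8,1,0,0,0
"COC(=O)C",5,6,1,3,3,0
"CCOC(=O)C",1,6,1,3,3,0
"CCOC(=O)C",2,6,2,2,2,0
"CCOC(=O)C",3,8,2,0,0,0
"CCOC(=O)C",4,6,3,0,0,0
"CCOC(=O)C",5,8,1,0,0,0
"CCOC(=O)C",6,6,1,3,3,0
"CCC(=O)OC",1,6,1,3,3,0
"CCC(=O)OC",2,6,2,2,2,0
"CCC(=O)OC",3,6,3,0,0,0
"CCC(=O)OC",4,8,1,0,0,0
"CCC(=O)OC",5,8,2,0,0,0
"CCC(=O)OC",6,6,1,3,3,0
"CCN",1,6,1,3,3,0
"CCN",2,6,2,2,2,0
"CCN",3,7,1,2,2,0
"CCCN",1,6,1,3,3,0
"CCCN",2,6,2,2,2,0
"CCCN",3,6,2,2,2,0
"CCCN",4,7,1,2,2,0
"CC(N)C",1,6,1,3,3,0
"CC(N)C",2,6,3,1,1,0
"CC(N)C",3,7,1,2,2,0
"CC(N)C",4,6,1,3,3,0
"CC#N",1,6,1,3,3,0
"CC#N",2,6,2,0,0,0
"CC#N",3,7,1,0,0,0
"CC(=O)N",1,6,1,3,3,0
"CC(=O)N",2,6,3,0,0,0
"CC(=O)N",3,8,1,0,0,0
"CC(=O)N",4,7,1,2,2,0
"CNC(=O)C",1,6,1,3,3,0
"CNC(=O)C",2,7,2,1,1,0
"CNC(=O)C",3,6,3,0,0,0
"CNC(=O)C",4,8,1,0,0,0
"CNC(=O)C",5,6,1,3,3,0
"CCS",1,6,1,3,3,0
"CCS",2,6,2,2,2,0
"CCS",3,16,1,1,1,0
"CSCC",1,6,1,3,3,0
"CSCC",2,16,2,0,0,0
"CSCC",3,6,2,2,2,0
"CSCC",4,6,1,3,3,0
"CC=C",1,6,1,3,3,0
"CC=C",2,6,2,1,1,0
"CC=C",3,6,1,2,2,0
"CC=CC",1,6,1,3,3,0
"CC=CC",2,6,2,1,1,0
"CC=CC",3,6,2,1,1,0
"CC=CC",4,6,1,3,3,0
"C#C",1,6,1,1,1,0
"C#C",2,6,1,1,1,0
"CC#C",1,6,1,3,3,0
"CC#C",2,6,2,0,0,0
"CC#C",3,6,1,1,1,0
"c1ccccc1",1,6,2,1,1,1
"c1ccccc1",2,6,2,1,1,1
"c1ccccc1",3,6,2,1,1,1
"c1ccccc1",4,6,2,1,1,1
"c1ccccc1",5,6,2,1,1,1
"c1ccccc1",6,6,2,1,1,1
"Cc1ccccc1",1,6,1,3,3,0
"Cc1ccccc1",2,6,3,0,0,1
"Cc1ccccc1",3,6,2,1,1,1
"Cc1ccccc1",4,6,2,1,1,1
"Cc1ccccc1",5,6,2,1,1,1
"Cc1ccccc1",6,6,2,1,1,1
"Cc1ccccc1",7,6,2,1,1,1
"CCc1ccccc1",1,6,1,3,3,0
"CCc1ccccc1",2,6,2,2,2,0
"CCc1ccccc1",3,6,3,0,0,1
"CCc1ccccc1",4,6,2,1,1,1
"CCc1ccccc1",5,6,2,1,1,1
"CCc1ccccc1",6,6,2,1,1,1
"CCc1ccccc1",7,6,2,1,1,1
"CCc1ccccc1",8,6,2,1,1,1
"c1cccnc1",1,6,2,1,1,1
"c1cccnc1",2,6,2,1,1,1
"c1cccnc1",3,6,2,1,1,1
"c1cccnc1",4,6,2,1,1,1
"c1cccnc1",5,7,2,0,0,1
"c1cccnc1",6,6,2,1,1,1
"Cc1ccncc1",1,6,1,3,3,0
"Cc1ccncc1",2,6,3,0,0,1
"Cc1ccncc1",3,6,2,1,1,1
"Cc1ccncc1",4,6,2,1,1,1
"Cc1ccncc1",5,7,2,0,0,1
"Cc1ccncc1",6,6,2,1,1,1
"Cc1ccncc1",7,6,2,1,1,1
"c1ccc2c(c1)cccc2",1,6,2,1,1,1
"c1ccc2c(c1)cccc2",2,6,2,1,1,1
"c1ccc2c(c1)cccc2",3,6,2,1,1,1
"c1ccc2c(c1)cccc2",4,6,3,0,0,1
"c1ccc2c(c1)cccc2",5,6,3,0,0,1
"c1ccc2c(c1)cccc2",6,6,2,1,1,1
"c1ccc2c(c1)cccc2",7,6,2,1,1,1
"c1ccc2c(c1)cccc2",8,6,2,1,1,1
"c1ccc2c(c1)cccc2",9,6,2,1,1,1
"c1ccc2c(c1)cccc2",10,6,2,1,1,1
"c1ccco1",1,6,2,1,1,1
"c1ccco1",2,6,2,1,1,1
"c1ccco1",3,6,2,1,1,1
"c1ccco1",4,6,2,1,1,1
"c1ccco1",5,8,2,0,0,1
"c1cccs1",1,6,2,1,1,1
"c1cccs1",2,6,2,1,1,1
"c1cccs1",3,6,2,1,1,1
"c1cccs1",4,6,2,1,1,1
"c1cccs1",5,16,2,0,0,1
"Oc1ccccc1",1,8,1,1,1,0
"Oc1ccccc1",2,6,3,0,0,1
"Oc1ccccc1",3,6,2,1,1,1
"Oc1ccccc1",4,6,2,1,1,1
"Oc1ccccc1",5,6,2,1,1,1
"Oc1ccccc1",6,6,2,1,1,1
"Oc1ccccc1",7,6,2,1,1,1
"COc1ccccc1",1,6,1,3,3,0
"COc1ccccc1",2,8,2,0,0,0
"COc1ccccc1",3,6,3,0,0,1
"COc1ccccc1",4,6,2,1,1,1
"COc1ccccc1",5,6,2,1,1,1
"COc1ccccc1",6,6,2,1,1,1
"COc1ccccc1",7,6,2,1,1,1
"COc1ccccc1",8,6,2,1,1,1
"Nc1ccccc1",1,7,1,2,2,0
"Nc1ccccc1",2,6,3,0,0,1
"Nc1ccccc1",3,6,2,1,1,1
"Nc1ccccc1",4,6,2,1,1,1
"Nc1ccccc1",5,6,2,1,1,1
"Nc1ccccc1",6,6,2,1,1,1
"Nc1ccccc1",7,6,2,1,1,1
"CC(=O)c1ccccc1",1,6,1,3,3,0
"CC(=O)c1ccccc1",2,6,3,0,0,0
"CC(=O)c1ccccc1",3,8,1,0,0,0
"CC(=O)c1ccccc1",4,6,3,0,0,1
"CC(=O)c1ccccc1",5,6,2,1,1,1
"CC(=O)c1ccccc1",6,6,2,1,1,1
"CC(=O)c1ccccc1",7,6,2,1,1,1
"CC(=O)c1ccccc1",8,6,2,1,1,1
"CC(=O)c1ccccc1",9,6,2,1,1,1
"COC(=O)c1ccccc1",1,6,1,3,3,0
"COC(=O)c1ccccc1",2,8,2,0,0,0
"COC(=O)c1ccccc1",3,6,3,0,0,0
"COC(=O)c1ccccc1",4,8,1,0,0,0
"COC(=O)c1ccccc1",5,6,3,0,0,1
"COC(=O)c1ccccc1",6,6,2,1,1,1
"COC(=O)c1ccccc1",7,6,2,1,1,1
"COC(=O)c1ccccc1",8,6,2,1,1,1
"COC(=O)c1ccccc1",9,6,2,1,1,1
"COC(=O)c1ccccc1",10,6,2,1,1,1
"C1CCCCC1",1,6,2,2,2,0
"C1CCCCC1",2,6,2,2,2,0
"C1CCCCC1",3,6,2,2,2,0
"C1CCCCC1",4,6,2,2,2,0
"C1CCCCC1",5,6,2,2,2,0
"C1CCCCC1",6,6,2,2,2,0
"C1CCCC1",1,6,2,2,2,0
"C1CCCC1",2,6,2,2,2,0
"C1CCCC1",3,6,2,2,2,0
"C1CCCC1",4,6,2,2,2,0
"C1CCCC1",5,6,2,2,2,0
"C1CCCO1",1,6,2,2,2,0
"C1CCCO1",2,6,2,2,2,0
"C1CCCO1",3,6,2,2,2,0
"C1CCCO1",4,6,2,2,2,0
"C1CCCO1",5,8,2,0,0,0
"CC1CCCCC1",1,6,1,3,3,0
"CC1CCCCC1",2,6,3,1,1,0
"CC1CCCCC1",3,6,2,2,2,0
"CC1CCCCC1",4,6,2,2,2,0
"CC1CCCCC1",5,6,2,2,2,0
"CC1CCCCC1",6,6,2,2,2,0
"CC1CCCCC1",7,6,2,2,2,0
"FC(F)F",1,9,1,0,0,0
"FC(F)F",2,6,3,1,1,0
"FC(F)F",3,9,1,0,0,0
"FC(F)F",4,9,1,0,0,0
"BrCCBr",1,35,1,0,0,0
"BrCCBr",2,6,2,2,2,0
"BrCCBr",3,6,2,2,2,0
"BrCCBr",4,35,1,0,0,0
"CCCl",1,6,1,3,3,0
"CCCl",2,6,2,2,2,0
"CCCl",3,17,1,0,0,0
"CCBr",1,6,1,3,3,0
"CCBr",2,6,2,2,2,0
"CCBr",3,35,1,0,0,0
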