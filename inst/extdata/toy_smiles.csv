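"id","smiles","label","expect_reason","expect_std"
"ethanol","CCO",0,"none","CCO"
"acetic_acid","CC(=O)O",0,"none","CC(=O)O"
"na_acetate","[Na+].CC(=O)[O-]",0,"none","CC(=O)O"
"ca_diacetate","CC(=O)[O-].CC(=O)[O-].[Ca+2]",0,"none","CC(=O)O"
"gly_hcl","Cl.NCC(=O)O",1,"none","NCC(=O)O"
"l_alanine","C[C@H](N)C(=O)O",1,"none","CC(C(=O)O)N"
"e_butene","C/C=C/C",0,"none","CC=CC"
"s_ibuprofen","CC(C)Cc1ccc(cc1)[C@@H](C)C(=O)O",0,"none","CC(Cc1ccc(cc1)C(C(=O)O)C)C"
"hydroxypyridine","Oc1ccccn1",1,"none","Oc1ccccn1"
"pyridone","O=c1cccc[nH]1",1,"none","Oc1ccccn1"
"ethylammonium","CC[NH3+]",0,"none","CCN"
"phenolate","[O-]c1ccccc1",0,"none","Oc1ccccc1"
"tma_chloride","C[N+](C)(C)C.[Cl-]",1,"none","C[N+](C)(C)C"
"benzene","c1ccccc1",0,"none","c1ccccc1"
"aspirin","CC(=O)Oc1ccccc1C(=O)O",0,"none","CC(=O)Oc1ccccc1C(=O)O"
"caffeine","Cn1cnc2c1c(=O)n(C)c(=O)n2C",1,"none","Cn1cnc2c1c(=O)n(C)c(=O)n2C"
"thiophenol","Sc1ccccc1",1,"none","Sc1ccccc1"
"acetonitrile","CC#N",0,"none","CC#N"
"pentane_ethane","CCCCC.CC",0,"none","CCCCC"
"silica","O=[Si]=O",0,"inorganic",""
"sodium_chloride","[Na+].[Cl-]",0,"inorganic",""
"tms_methane","C[Si](C)(C)C",0,"inorganic",""
"garbage","xyzzy!",0,"parse_failure",""
"proton","[H+]",0,"empty_after_salt_strip",""
"long_alkane","CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",0,"too_long",""
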