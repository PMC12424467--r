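name,smiles,mass,hbd,hba,tpsa
water,O,18.010565,1,1,31.5
methanol,CO,32.026215,1,1,20.23
ethanol,CCO,46.041865,1,1,20.23
acetone,CC(C)=O,58.041865,0,1,17.07
acetonitrile,CC#N,41.026549,0,1,23.79
dmso,CS(C)=O,78.013936,0,1,17.07
hexane,CCCCCC,86.10955,0,0,0.0
heptane,CCCCCCC,100.125201,0,0,0.0
octanol,CCCCCCCCO,130.135765,1,1,20.23
benzene,c1ccccc1,78.04695,0,0,0.0
toluene,Cc1ccccc1,92.0626,0,0,0.0
naphthalene,c1ccc2ccccc2c1,128.0626,0,0,0.0
thf,C1CCOC1,72.057515,0,1,9.23
dioxane,C1COCCO1,88.052429,0,2,18.46
chloroform,ClC(Cl)Cl,117.914383,0,0,0.0
dichloromethane,ClCCl,83.953355,0,0,0.0
phenol,Oc1ccccc1,94.041865,1,1,20.23
aniline,Nc1ccccc1,93.057849,1,1,26.02
pyridine,c1ccncc1,79.042199,0,1,12.89
imidazole,c1c[nH]cn1,68.037448,1,2,28.68
nitrobenzene,O=[N+]([O-])c1ccccc1,123.032028,0,3,43.14
benzoic_acid,OC(=O)c1ccccc1,122.036779,1,2,37.3
methyl_benzoate,COC(=O)c1ccccc1,136.052429,0,2,26.3
urea,NC(N)=O,60.032363,2,3,69.11
glycerol,OCC(O)CO,92.047344,3,3,60.69
glucose,OCC1OC(O)C(O)C(O)C1O,180.063388,5,6,110.38
citric_acid,OC(=O)CC(O)(CC(O)=O)C(O)=O,192.027003,4,7,132.13
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,194.080376,0,6,61.82
paracetamol,CC(=O)Nc1ccc(O)cc1,151.063329,2,3,49.33
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,206.13068,1,2,37.3
aspirin,CC(=O)Oc1ccccc1C(=O)O,180.042259,1,4,63.6
metformin,CN(C)C(=N)NC(=N)N,129.101445,4,5,88.99
atrazine,CCNc1nc(Cl)nc(NC(C)C)n1,215.093773,2,5,62.73
carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21,236.094963,1,3,46.33
diclofenac,OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl,295.016684,2,3,49.33
sulfamethoxazole,Cc1cc(no1)NS(=O)(=O)c1ccc(N)cc1,253.052112,2,6,98.22
deet,CCN(CC)C(=O)c1cccc(C)c1,191.131014,0,2,20.31
bisphenol_a,CC(C)(c1ccc(O)cc1)c1ccc(O)cc1,228.11503,2,2,40.46
triclosan,Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl,287.951163,1,2,29.46
tfa,OC(=O)C(F)(F)F,113.992864,1,2,37.3
pfoa,OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,413.973703,1,2,37.3
pfbs,OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F,299.950269,1,3,54.37
caprolactam,O=C1CCCCCN1,113.084064,1,2,29.1
taurine,NCCS(O)(=O)=O,125.014664,2,4,80.39
benzamide,NC(=O)c1ccccc1,121.052764,1,2,43.09
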