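# Synthetic stand-in validation set: 73 approved small-molecule drugs drawn
# from the public top-200 US prescription universe, hand-curated for this
# package's batch-validation protocol. This file is NOT the original
# supplementary reference set of any publication; structures were written
# from public knowledge and are stereo-free.
CCOC(=O)C1=C(COCCN)NC(C)=C(C1c1ccccc1Cl)C(=O)OC amlodipine
CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O atorvastatin
CCCCc1nc(Cl)c(CO)n1Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1 losartan
COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1 omeprazole
CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12 simvastatin
Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1 celecoxib
CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21 sertraline
CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1 fluoxetine
CN(C)CCCC1(c2ccc(F)cc2)OCc2cc(C#N)ccc21 citalopram
CNCCC(Oc1cccc2ccccc12)c1cccs1 duloxetine
CN(C)CC(c1ccc(OC)cc1)C1(O)CCCCC1 venlafaxine
CC(NC(C)(C)C)C(=O)c1cccc(Cl)c1 bupropion
Cc1nnc2n1-c1ccc(Cl)cc1C(c1ccccc1)=NC2 alprazolam
OCCOCCN1CCN(C2=Nc3ccccc3Sc3ccccc32)CC1 quetiapine
O=C1CCc2cc(OCCCCN3CCN(c4cccc(Cl)c4Cl)CC3)ccc2N1 aripiprazole
CC1=C(CCN2CCC(c3noc4cc(F)ccc34)CC2)C(=O)N2CCCCC2=N1 risperidone
CCCc1nn(C)c2c(=O)[nH]c(-c3cc(S(=O)(=O)N4CCN(C)CC4)ccc3OCC)nc12 sildenafil
CN1CC(=O)N2C(Cc3c([nH]c4ccccc34)C2c2ccc3OCOc3c2)C1=O tadalafil
CCOC(=O)N1CCC(=C2c3ccc(Cl)cc3CCc3cccnc32)CC1 loratadine
OC(=O)COCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1 cetirizine
CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1 ranitidine
COc1ccnc(CS(=O)c2nc3cc(OC(F)F)ccc3[nH]2)c1OC pantoprazole
COCCc1ccc(OCC(O)CNC(C)C)cc1 metoprolol
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol
COc1ccccc1OCCNCC(O)COc1cccc2[nH]c3ccccc3c12 carvedilol
CC(C)NCC(O)COc1cccc2ccccc12 propranolol
CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O amoxicillin
CC1=C(C(=O)O)N2C(=O)C(NC(=O)C(N)c3ccccc3)C2SC1 cephalexin
OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O ciprofloxacin
CC1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(=O)O)cn1c23 levofloxacin
COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC trimethoprim
Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1 sulfamethoxazole
OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F fluconazole
NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O hydrochlorothiazide
NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl furosemide
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O warfarin
COC(=O)C(c1ccccc1Cl)N1CCc2sccc2C1 clopidogrel
COc1ccc(-n2nc(C(N)=O)c3CCN(c4ccc(N5CCCCC5=O)cc4)C(=O)c23)cc1 apixaban
O=C(NCC1CN(c2ccc(N3CCOCC3=O)cc2)C(=O)O1)c1ccc(Cl)s1 rivaroxaban
Cc1cnc(C(=O)NCCc2ccc(S(=O)(=O)NC(=O)NC3CCCCC3)cc2)cn1 glipizide
COc1ccc(Cl)cc1C(=O)NCCc1ccc(S(=O)(=O)NC(=O)NC2CCCCC2)cc1 glyburide
CCc1ccc(CCOc2ccc(CC3SC(=O)NC3=O)cc2)nc1 pioglitazone
NC(CC(=O)N1CCn2c(nnc2C(F)(F)F)C1)Cc1cc(F)c(F)cc1F sitagliptin
CCOC(=O)C(CCc1ccccc1)NC(C)C(=O)N1CCCC1C(=O)O enalapril
CCCCC(=O)N(Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1)C(C(C)C)C(=O)O valsartan
CCCCC1=NC2(CCCC2)C(=O)N1Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1 irbesartan
CCCCc1oc2ccccc2c1C(=O)c1cc(I)c(OCCN(CC)CC)c(I)c1 amiodarone
COc1ccc(C2Sc3ccccc3N(CCN(C)C)C(=O)C2OC(C)=O)cc1 diltiazem
COc1ccc(CCN(C)CCCC(C#N)(C(C)C)c2ccc(OC)c(OC)c2)cc1OC verapamil
CC(C)c1nc(N(C)S(C)(=O)=O)nc(-c2ccc(F)cc2)c1C=CC(O)CC(O)CC(=O)O rosuvastatin
OC(CCC1C(=O)N(c2ccc(F)cc2)C1c1ccc(O)cc1)c1ccc(F)cc1 ezetimibe
CC(C)OC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1 fenofibrate
Cc1ccc(C)c(OCCCC(C)(C)C(=O)O)c1 gemfibrozil
COc1ccc2cc(C(C)C(=O)O)ccc2c1 naproxen
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl diclofenac
COc1cccc(C2(O)CCCCC2CN(C)C)c1 tramadol
Cc1nccn1CC1CCc2c(C1=O)c1ccccc1n2C ondansetron
CNS(=O)(=O)Cc1ccc2[nH]cc(CCN(C)C)c2c1 sumatriptan
CN(C)CCc1c[nH]c2ccc(Cn3cncn3)cc12 rizatriptan
Cc1ccc(-c2nc3ccc(C)cn3c2CC(=O)N(C)C)cc1 zolpidem
OC1N=C(c2ccccc2Cl)c2cc(Cl)ccc2NC1=O lorazepam
O=C1CN=C(c2ccccc2Cl)c2cc([N+](=O)[O-])ccc2N1 clonazepam
CN1c2ccc(Cl)cc2C(c2ccccc2)=NCC1=O diazepam
O=C1CC2(CCCC2)CC(=O)N1CCCCN1CCN(c2ncccn2)CC1 buspirone
OCCOCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1 hydroxyzine
Cc1cccc(CN2CCN(C(c3ccccc3)c3ccc(Cl)cc3)CC2)c1 meclizine
COc1cc2CC(CC3CCN(Cc4ccccc4)CC3)C(=O)c2cc1OC donepezil
CC12CC3CC(C)(C1)CC(N)(C3)C2 memantine
CCOc1ccccc1OCCNC(C)Cc1ccc(OC)c(S(N)(=O)=O)c1 tamsulosin
OC(C(=O)OCC#CCN(CC)CC)(c1ccccc1)C1CCCCC1 oxybutynin
Clc1cccc(Cl)c1NC1=NCCN1 clonidine
Brc1c(NC2=NCCN2)ccc2nccnc12 brimonidine
Clc1ccc2nsnc2c1NC1=NCCN1 tizanidine
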