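code,concept,record_kind,class
AST01,asthma_dx,event,
AST02,asthma_dx,event,
AST03,asthma_dx,event,
CPD01,copd_dx,event,
CPD02,copd_dx,event,
CPD03,copd_dx,event,
CF01,cystic_fibrosis_dx,event,
LCA01,lung_cancer_dx,event,
LCA02,lung_cancer_dx,event,
BRX01,bronchiectasis_dx,event,
FIB01,fibrotic_lung_dx,event,
FIB02,fibrotic_lung_dx,event,
MI01,mi_dx,event,
MI02,mi_dx,event,
HTN01,hypertension_dx,event,
HTN02,hypertension_dx,event,
STR01,stroke_dx,event,
STR02,stroke_dx,event,
HF01,heart_failure_dx,event,
HF02,heart_failure_dx,event,
SAB01,saba,prescription,SABA
SAB02,saba,prescription,SABA
SAB03,saba,prescription,SABA
LAB01,laba,prescription,LABA
LAB02,laba,prescription,LABA
LAB03,laba,prescription,LABA
LAM01,lama,prescription,LAMA
LAM02,lama,prescription,LAMA
LAM03,lama,prescription,LAMA
ICS01,ics,prescription,ICS
ICS02,ics,prescription,ICS
ICS03,ics,prescription,ICS
CMB01,ics_laba,prescription,ICS/LABA
CMB02,ics_laba,prescription,ICS/LABA
CMB03,ics_laba,prescription,ICS/LABA
LTR01,ltra,prescription,LTRA
LTR02,ltra,prescription,LTRA
OCS01,ocs,prescription,OCS
OCS02,ocs,prescription,OCS
OCS03,ocs,prescription,OCS
ABX01,antibiotic,prescription,ABX
ABX02,antibiotic,prescription,ABX
ABX03,antibiotic,prescription,ABX
ABX04,antibiotic,prescription,ABX
GPV01,gp_visit,event,
GPV02,gp_visit,event,
RAD01,resp_admission,event,
RAD02,resp_admission,event,
RAD03,resp_admission,event,
NAD01,nonresp_admission,event,
NAD02,nonresp_admission,event,
NAD03,nonresp_admission,event,
FEV01,fev1,event,
FVP01,fev1_pct_pred,event,
PEF01,pef,event,
SMK01,smoking_status,event,
SMK02,smoking_status,event,
BMI01,bmi,event,
DTH01,death,event,
DRG01,deregistration,event,
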