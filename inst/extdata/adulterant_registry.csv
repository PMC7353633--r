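code,name,category,nitrogen_fraction,protein_fraction,solids_fraction,molar_mass,dissociation_count
WMP,whole milk powder,protein_rich,0,0.26,0.97,0,0
SMP,skimmed milk powder,protein_rich,0,0.34,0.96,0,0
WPI,whey protein isolate,protein_rich,0,0.90,0.95,0,0
PEA,pea protein isolate,protein_rich,0,0.80,0.94,0,0
SOY,soy protein isolate,protein_rich,0,0.90,0.94,0,0
URE,urea,nitrogen,0.467,0,1,60.06,1
MLM,melamine,nitrogen,0.667,0,1,126.12,1
AS,ammonium sulphate,nitrogen,0.212,0,1,132.14,3
AC,ammonium chloride,nitrogen,0.262,0,1,53.49,2
DIC,dicyandiamide,nitrogen,0.666,0,1,84.08,1
SU,sucrose,carbohydrate,0,0,1,342.30,1
GLU,glucose,carbohydrate,0,0,1,180.16,1
ST,corn starch,carbohydrate,0,0,1,0,0
LAC,lactose,carbohydrate,0,0,1,342.30,1
FRU,fructose,carbohydrate,0,0,1,180.16,1
MD,maltodextrin,carbohydrate,0,0,1,0,0
AR,arrowroot powder,carbohydrate,0,0,1,0,0
CIT,sodium citrate,preservative,0,0,1,258.07,4
CAR,sodium carbonate,preservative,0,0,1,105.99,3
BIC,sodium bicarbonate,preservative,0,0,1,84.01,2
HYD,sodium hydroxide,preservative,0,0,1,40.00,2
FMD,formaldehyde,preservative,0,0,0,30.03,1
PX,hydrogen peroxide,preservative,0,0,0,34.01,1
WATER,water,water,0,0,0,0,0
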