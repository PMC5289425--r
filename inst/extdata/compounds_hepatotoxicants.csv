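id,parent_id,mw_g_mol,logp,fu,compound_type,pka1,pka2,solubility_mg_l
APAP,,151.16,0.33,0.81,acid,9.38,,14000
APAP-cysteine,APAP,254.31,0.40,0.6,zwitterion,1.93,9.09,337
APAP-glucuronide,APAP,327.29,-0.98,0.98,acid,3.17,,27700
APAP-sulfate,APAP,231.23,-0.52,0.80,zwitterion,-2.16,14.65,1540
NAPQI,APAP,149.15,0.1,0.02,neutral,,,987
AD,,645.31,4.67,0.0032,base,6.56,,4.76
6-MP,AZA,152.18,1.85,0.81,zwitterion,9.50,2.99,68500
AZA,,277.26,0.10,0.70,base,7.87,,1007
CPA,,261.09,0.80,0.80,acid,6.00,,30000
CSA,,1202.61,3.88,0.09,base,11.83,,5.81
DFN,,296.15,4.10,0.0035,acid,4.15,,2.37
ERY,,733.93,3.06,0.18,base,8.88,,2000
ERY-PED,ERY,862.06,3.84,0.18,acid,7.10,,2000
2-hydroxy-FT,FT,292.21,2.08,0.028,acid,3.80,,5.56
FT,,276.21,3.05,0.052,base,13.17,,9.45
HPL,,375.86,3.60,0.06,base,8.66,,14.00
Acetyl-INH,INH,179.18,-0.90,0.90,zwitterion,6.77,3.02,1770
INH,,137.14,-0.67,0.90,zwitterion,13.61,3.35,140000
PB,,232.24,0.13,0.57,acid,7.30,,1110
PHE,,252.27,2.26,0.098,acid,8.33,,32.00
RIF,,822.94,2.93,0.195,acid,1.70,,1400
SST,,418.57,4.68,0.03,neutral,,,0.76
SST-acid,SST,436.58,4.3,0.056,acid,4.31,,11.00
Hydroxy-VPA,VPA,160.21,1.42,0.04,acid,4.81,,45100
VPA,,114.21,1.85,0.04,acid,5.14,,1300
VPA-glucuronide,VPA,320.33,0.85,0.04,acid,3.41,,22200
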