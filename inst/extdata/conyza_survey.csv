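population,habitat,region,n_treated,n_survived,R_printed,county,gwpa_km2
A1,orchard,northern,89,3,0.03,Butte,3
A2,orchard,northern,60,4,0.07,Butte,3
B1,orchard,northern,60,8,0.13,Butte,3
B2,orchard,northern,52,0,0.00,Butte,3
B3,orchard,northern,50,1,0.02,Sutter,224
C1,orchard,northern,40,0,0.00,Colusa,5
C2,orchard,northern,60,1,0.02,Colusa,5
YOL2,orchard,northern,60,14,0.23,Yolo,78
SON1,vineyard,northern,78,10,0.11,Sonoma,36
E1,vineyard,central,50,27,0.53,San Joaquin,683
E2,vineyard,central,54,54,1.00,San Joaquin,683
F2,orchard,central,51,50,0.98,San Joaquin,683
G2,orchard,central,67,59,0.86,Stanislaus,1219
G3,orchard,central,82,3,0.04,Stanislaus,1219
H1,orchard,southern,51,39,0.78,Madera,523
H2,orchard,southern,56,55,0.95,Madera,523
H3,vineyard,southern,89,88,0.99,Madera,523
I1,vineyard,southern,42,42,1.00,Madera,523
I2,vineyard,southern,71,41,0.53,Madera,523
I3,vineyard,southern,60,51,0.85,Madera,523
K1,vineyard,southern,77,77,1.00,Fresno,1461
K2,vineyard,southern,51,26,0.58,Fresno,1461
K3,vineyard,southern,75,70,0.94,Fresno,1461
L1,vineyard,southern,60,60,1.00,Tulare,1609
L2,vineyard,southern,60,60,1.00,Tulare,1609
N1,vineyard,southern,51,50,0.98,Kern,42
CSU,orchard,southern,NA,NA,NA,Fresno,1461
WES,vineyard,southern,NA,NA,NA,Fresno,1461
MCC,vineyard,southern,NA,NA,NA,Fresno,1461
KEA,vineyard,southern,NA,NA,NA,Fresno,1461
MEN2,roadside,nonagricultural,60,0,0.00,Mendocino,3
AUB1,roadside,nonagricultural,90,3,0.03,Placer,140
YOL1,roadside,nonagricultural,51,2,0.04,Yolo,78
MEN1,roadside,nonagricultural,27,9,0.33,Mendocino,3
SAC1,roadside,nonagricultural,60,2,0.03,Sacramento,395
NAP1,roadside,nonagricultural,57,0,0.00,Napa,0
BOD1,roadside,nonagricultural,47,0,0.00,Sonoma,36
BOD2,roadside,nonagricultural,67,13,0.14,Sonoma,36
LIV1,roadside,nonagricultural,60,1,0.02,Alameda,0
MAR,roadside,nonagricultural,59,1,0.02,Mariposa,0
CRU1,reserve,nonagricultural,54,4,0.07,Santa Cruz,0
MON2,roadside,nonagricultural,90,16,0.18,Monterey,156
R,control_resistant,control,193,185,0.96,Tulare,1609
S,control_susceptible,control,255,10,0.02,Fresno,1461
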