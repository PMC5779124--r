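population,n,A,HE,HO,FIS,s_printed
A1,30,2.5,0.33,0.06,0.837,0.911
A2,28,3,0.33,0.01,0.978,0.989
B1,30,3.7,0.37,0,1,1
B2,28,2.1,0.19,0,1,1
B3,30,1.7,0.2,0.02,0.914,0.955
C1,23,2.1,0.19,0.01,0.979,0.989
C2,29,2.4,0.25,0,1,1
YOL2,30,2.3,0.21,0.01,0.712,0.832
SON1,30,2.7,0.42,0.04,0.875,0.933
E1,29,1.6,0.04,0,1,1
E2,30,2.2,0.28,0.01,0.952,0.976
F2,30,1.1,0,0,-0.009,-0.017
G2,27,2.2,0.15,0,1,1
G3,30,2.4,0.12,0,1,1
H1,30,2.9,0.34,0,1,1
H2,30,1.9,0.06,0,1,1
H3,30,1.9,0.06,0,1,1
I1,30,2.8,0.4,0,0.994,0.997
I2,29,2.1,0.17,0.01,0.969,0.984
I3,30,2,0.08,0.01,0.947,0.973
K1,30,2.2,0.32,0.02,0.954,0.976
K2,30,2.2,0.31,0.02,0.947,0.973
K3,28,2.2,0.31,0.01,0.977,0.988
L1,30,2.4,0.3,0.02,0.942,0.97
L2,30,4.3,0.45,0.01,0.987,0.994
N1,30,2.6,0.31,0.03,0.817,0.9
CSU,30,1.8,0.27,0.02,0.918,0.957
WES,30,2.1,0.35,0.1,0.685,0.813
MCC,30,1.8,0.24,0,0.97,0.985
KEA,30,1,0,0,NA,NA
MEN2,29,2.4,0.23,0.02,0.906,0.951
AUB1,30,1.4,0.11,0,1,1
YOL1,30,2.2,0.22,0,0.991,0.995
MEN1,30,1.3,0.02,0,0.831,0.908
SAC1,30,1.9,0.2,0.01,0.778,0.875
NAP1,30,1.8,0.08,0.01,0.933,0.965
BOD1,30,1,0,0,NA,NA
BOD2,30,2.6,0.32,0,0.982,0.991
LIV1,30,1.9,0.35,0.01,0.983,0.991
MAR,30,1.6,0.11,0.01,0.906,0.95
CRU1,30,1.9,0.24,0.01,0.973,0.986
MON2,30,1.9,0.16,0.02,0.629,0.773
R,30,1,0,0,NA,NA
S,30,1,0,0,NA,NA
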