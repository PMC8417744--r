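drug_id,drug_name,hypoxia_alone,hypoxia_combo,hypoxia_bliss,normoxia_alone,normoxia_combo,normoxia_bliss
S1150,Paclitaxel,0.420,0.303,0.075,0.389,0.332,0.011
S1526,AC220,1.101,0.855,0.134,0.982,0.741,0.128
S1241,Vincristine,0.324,0.216,0.074,0.334,0.289,0.006
S2679,Flavopiridol HCl,0.722,0.728,-0.079,0.441,0.499,-0.109
S2634,Rebastinib,1.022,0.815,0.104,1.053,0.797,0.133
S1001,Navitoclax,1.019,0.797,0.118,0.928,0.761,0.059
S1165,ABT-751 (E7010),0.932,0.737,0.101,0.898,0.794,-0.001
S1018,Dovitinib,1.080,0.864,0.107,0.995,0.875,0.004
S1109,BI 2536,0.436,0.297,0.094,0.464,0.391,0.019
S1148,Docetaxel,0.432,0.294,0.094,0.385,0.330,0.010
S1039,Rapamycin,1.073,0.829,0.136,0.828,0.671,0.061
S1010,Nintedanib,1.129,0.787,0.228,0.983,0.803,0.066
S1452,Ispinesib,0.433,0.277,0.111,0.434,0.368,0.016
S2700,KX2-391,0.371,0.234,0.100,0.397,0.364,-0.013
S4902,QNZ (EVP4593),1.004,0.522,0.381,0.917,0.772,0.038
S2193,GSK461364,0.462,0.316,0.100,0.477,0.405,0.017
S2198,SGI-1776 free base,1.086,0.851,0.125,1.025,0.798,0.108
S2201,BMS-794833,1.155,0.899,0.139,1.048,0.927,-0.001
S2235,Volasertib (BI 6727),0.452,0.288,0.118,0.477,0.380,0.042
S2775,Nocodazole,0.392,0.228,0.124,0.411,0.358,0.005
S8048,Venetoclax,1.003,0.765,0.136,0.908,0.752,0.050
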