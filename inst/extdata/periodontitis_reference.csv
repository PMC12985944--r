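protein,full_name,mean_nor,mean_cp,effect,p_value,n_nor,n_cp,fdr
GDF15,Growth differentiation factor 15,-0.183,0.157,0.337,1.31e-15,2223,89,2.82e-12
IGFBP4,Insulin-like growth factor-binding protein 4,-0.146,0.127,0.269,1.05e-9,2177,87,1.13e-6
RBFOX3,RNA binding fox-1 homolog 3,-0.102,0.121,0.227,4.23e-9,2225,90,3.03e-6
COL6A3,Collagen type VI alpha 3 chain,-0.091,0.128,0.218,9.90e-9,2223,89,4.76e-6
TNFRSF10B,Tumor necrosis factor receptor superfamily member 10B,-0.105,0.164,0.269,1.11e-8,2222,87,4.76e-6
SHISA5,Shisa family member 5,-0.073,0.069,0.142,1.52e-8,2227,90,5.46e-6
ADM,Adrenomedullin,-0.152,0.050,0.200,2.46e-8,2234,89,7.57e-6
LTBR,Lymphotoxin beta receptor,-0.048,0.123,0.172,4.27e-8,2196,89,1.15e-5
NT-proBNP,N-terminal pro-B-type natriuretic peptide,-0.250,0.366,0.594,5.45e-8,2212,86,1.30e-5
RNASE1,Ribonuclease A family member 1,-0.049,0.086,0.136,7.92e-8,2226,89,1.55e-5
TNFRSF1A,Tumor necrosis factor receptor superfamily member 1A,-0.084,0.088,0.172,8.26e-8,2208,88,1.55e-5
LGALS9,Galectin 9,-0.116,0.084,0.197,8.67e-8,2211,89,1.55e-5
EGFR,Epidermal growth factor receptor,0.048,-0.050,-0.098,1.14e-7,2223,89,1.88e-5
VSIG4,V-set and immunoglobulin domain containing 4,-0.127,0.106,0.231,1.48e-7,2208,88,2.28e-5
FSTL3,Follistatin-like 3,-0.104,0.083,0.185,1.70e-7,2205,90,2.35e-5
IL-6,Interleukin 6,-0.128,0.324,0.450,1.75e-7,2212,89,2.35e-5
NPC2,NPC intracellular cholesterol transporter 2,-0.081,0.080,0.159,1.99e-7,2191,89,2.52e-5
COLEC12,Collectin subfamily member 12,-0.090,0.064,0.151,2.28e-7,2206,90,2.67e-5
TNFRSF1B,Tumor necrosis factor receptor superfamily member 1B,-0.084,0.106,0.189,2.36e-7,2208,88,2.67e-5
ADAM12,ADAM metallopeptidase domain 12,-0.048,0.140,0.184,2.73e-7,2161,88,2.91e-5
LAIR1,Leukocyte associated immunoglobulin-like receptor 1,-0.107,0.142,0.248,2.84e-7,2206,90,2.91e-5
CST3,Cystatin C,-0.086,0.071,0.160,3.04e-7,2205,89,2.97e-5
PRAP1,Proline-rich acidic protein 1,-0.132,0.097,0.238,3.34e-7,2227,90,3.12e-5
DNER,Delta and notch-like epidermal growth factor-related receptor,0.086,-0.080,-0.164,3.82e-7,2210,90,3.43e-5
SORCS2,Sortilin-related VPS10 domain containing receptor 2,-0.098,0.104,0.202,7.13e-7,2180,85,6.13e-5
TNFRSF10A,Tumor necrosis factor receptor superfamily member 10A,-0.091,0.093,0.180,7.54e-7,2222,87,6.24e-5
SCARB2,Scavenger receptor class B member 2,-0.087,0.071,0.154,7.87e-7,2184,84,6.27e-5
PGF,Placenta growth factor,-0.069,0.066,0.135,1.08e-6,2232,88,8.28e-5
RNASE6,Ribonuclease A family member K6,-0.071,0.072,0.143,1.14e-6,2216,89,8.48e-5
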