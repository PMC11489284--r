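species,element,treatment,median,q25,q75
O_bicornis,N,aCO2,3.02,2.92,3.15
O_bicornis,N,eCO2,2.93,2.74,3.54
O_bicornis,P,aCO2,4.53,3.86,5.07
O_bicornis,P,eCO2,5.68,2.99,7.42
O_bicornis,S,aCO2,1.03,0.96,1.14
O_bicornis,S,eCO2,1.15,1.06,1.27
O_bicornis,K,aCO2,1.15,0.91,1.25
O_bicornis,K,eCO2,1.29,1.02,1.37
O_bicornis,Na,aCO2,0.91,0.78,1.13
O_bicornis,Na,eCO2,1.10,0.88,1.32
O_bicornis,Ca,aCO2,1.18,0.98,1.49
O_bicornis,Ca,eCO2,1.15,0.89,1.47
O_bicornis,Mg,aCO2,1.12,1.00,1.24
O_bicornis,Mg,eCO2,1.06,0.97,1.17
O_bicornis,Cu,aCO2,0.79,0.66,0.93
O_bicornis,Cu,eCO2,0.84,0.69,0.97
O_bicornis,Zn,aCO2,2.89,2.56,3.18
O_bicornis,Zn,eCO2,2.96,2.61,3.36
O_bicornis,Fe,aCO2,0.97,0.87,1.03
O_bicornis,Fe,eCO2,1.14,1.05,1.24
O_bicornis,Mn,aCO2,0.44,0.34,0.51
O_bicornis,Mn,eCO2,0.56,0.40,0.72
A_mellifera,N,aCO2,2.48,2.39,2.61
A_mellifera,N,eCO2,2.43,2.26,2.89
A_mellifera,P,aCO2,3.48,2.84,3.93
A_mellifera,P,eCO2,4.20,2.31,5.67
A_mellifera,S,aCO2,2.94,2.71,3.18
A_mellifera,S,eCO2,3.29,3.06,3.55
A_mellifera,K,aCO2,0.87,0.82,0.93
A_mellifera,K,eCO2,0.97,0.91,1.02
A_mellifera,Na,aCO2,2.39,2.12,3.07
A_mellifera,Na,eCO2,2.82,2.26,3.52
A_mellifera,Ca,aCO2,0.13,0.11,0.15
A_mellifera,Ca,eCO2,0.12,0.10,0.15
A_mellifera,Mg,aCO2,0.30,0.26,0.34
A_mellifera,Mg,eCO2,0.29,0.25,0.32
A_mellifera,Cu,aCO2,1.14,1.05,1.22
A_mellifera,Cu,eCO2,1.20,1.09,1.30
A_mellifera,Zn,aCO2,1.29,1.14,1.43
A_mellifera,Zn,eCO2,1.32,1.16,1.48
A_mellifera,Fe,aCO2,0.79,0.70,0.86
A_mellifera,Fe,eCO2,0.93,0.84,1.03
A_mellifera,Mn,aCO2,0.006,0.005,0.007
A_mellifera,Mn,eCO2,0.009,0.006,0.010
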