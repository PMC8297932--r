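insecticide,strain,slope,slope_se,lc50,fl_lower,fl_upper
abamectin,WH-S,3.06,0.44,0.31,0.25,0.44
abamectin,WH-EB,2.60,0.36,13.89,10.86,19.10
abamectin,dA40-A98,2.53,0.34,0.26,0.20,0.35
abamectin,dA40-A107,2.26,0.33,15.72,11.93,22.93
abamectin,dA107-A98,4.23,0.66,0.45,0.37,0.56
abamectin,dA186,3.92,0.59,0.52,0.43,0.68
emamectin_benzoate,WH-S,2.57,0.35,0.0017,0.0014,0.0022
emamectin_benzoate,WH-EB,3.39,0.48,0.45,0.37,0.58
emamectin_benzoate,dA40-A98,3.33,0.51,0.0018,0.0014,0.0023
emamectin_benzoate,dA40-A107,2.60,0.33,0.33,0.26,0.43
emamectin_benzoate,dA107-A98,3.37,0.56,0.0017,0.0014,0.0021
emamectin_benzoate,dA186,2.46,0.33,0.0019,0.0015,0.0024
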