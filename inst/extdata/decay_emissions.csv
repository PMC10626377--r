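nuclide,half_life,half_life_unit,daughter,branching,emission_kind,energy_mev,yield,provenance
Lu-177,6.647,d,Hf-177,1,beta_mean,0.14935,0.794,ENSDF-style beta branch (Emax 498 keV)
Lu-177,6.647,d,Hf-177,1,beta_mean,0.11169,0.090,ENSDF-style beta branch (Emax 385 keV)
Lu-177,6.647,d,Hf-177,1,beta_mean,0.04766,0.1161,ENSDF-style beta branch (Emax 177 keV)
Lu-177,6.647,d,Hf-177,1,beta_mean,0.06690,0.00105,ENSDF-style beta branch (sub-1% yield)
Lu-177,6.647,d,Hf-177,1,gamma,0.20837,0.1036,ENSDF-style gamma line
Lu-177,6.647,d,Hf-177,1,gamma,0.11295,0.0617,ENSDF-style gamma line
Lu-177,6.647,d,Hf-177,1,gamma,0.24967,0.00205,ENSDF-style gamma line
Lu-177,6.647,d,Hf-177,1,gamma,0.32132,0.00216,ENSDF-style gamma line
Lu-177,6.647,d,Hf-177,1,xray,0.05500,0.0041,representative K x-ray group
Lu-177,6.647,d,Hf-177,1,conversion_electron,0.04970,0.0520,CE-K of 113 keV transition
Lu-177,6.647,d,Hf-177,1,conversion_electron,0.14480,0.0075,CE-K of 208 keV transition
Lu-177,6.647,d,Hf-177,1,auger,0.00650,0.1200,Auger electron group (mean)
Hf-177,,,,,none,,,stable
Ac-225,9.920,d,Fr-221,1,alpha,5.83000,0.507,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.79400,0.181,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.79000,0.086,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.73200,0.080,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.72400,0.031,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.63700,0.044,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.68200,0.013,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.60900,0.011,ENSDF-style alpha line
Ac-225,9.920,d,Fr-221,1,alpha,5.58000,0.006,ENSDF-style alpha line (sub-1% yield)
Ac-225,9.920,d,Fr-221,1,alpha,5.28600,0.002,ENSDF-style alpha line (sub-1% yield)
Ac-225,9.920,d,Fr-221,1,gamma,0.09980,0.0100,ENSDF-style gamma line
Ac-225,9.920,d,Fr-221,1,gamma,0.15010,0.0055,ENSDF-style gamma line
Ac-225,9.920,d,Fr-221,1,gamma,0.06280,0.0027,ENSDF-style gamma line
Fr-221,4.801,min,At-217,1,alpha,6.34100,0.834,ENSDF-style alpha line
Fr-221,4.801,min,At-217,1,alpha,6.12600,0.151,ENSDF-style alpha line
Fr-221,4.801,min,At-217,1,alpha,6.24300,0.0134,ENSDF-style alpha line
Fr-221,4.801,min,At-217,1,gamma,0.21810,0.1140,218 keV line used for Ac-225 counting window
Fr-221,4.801,min,At-217,1,gamma,0.40980,0.0015,ENSDF-style gamma line
At-217,0.0326,s,Bi-213,1,alpha,7.06700,0.999,ENSDF-style alpha line
At-217,0.0326,s,Bi-213,1,alpha,6.81300,0.001,ENSDF-style alpha line (sub-1% yield)
Bi-213,45.61,min,Po-213,0.9784,beta_mean,0.49200,0.6590,ENSDF-style beta branch (Emax 1423 keV)
Bi-213,45.61,min,Po-213,0.9784,beta_mean,0.32000,0.3090,ENSDF-style beta branch (Emax 983 keV)
Bi-213,45.61,min,Po-213,0.9784,beta_mean,0.13300,0.0104,ENSDF-style beta branch
Bi-213,45.61,min,Tl-209,0.0216,alpha,5.87500,0.0194,ENSDF-style alpha line
Bi-213,45.61,min,Tl-209,0.0216,alpha,5.55800,0.0018,ENSDF-style alpha line (sub-1% yield)
Bi-213,45.61,min,Po-213,0.9784,gamma,0.44045,0.2590,ENSDF-style gamma line
Bi-213,45.61,min,Po-213,0.9784,gamma,0.80740,0.0029,ENSDF-style gamma line
Po-213,3.72e-6,s,Pb-209,1,alpha,8.37600,1.000,ENSDF-style alpha line
Tl-209,2.162,min,Pb-209,1,beta_mean,0.65900,0.990,ENSDF-style beta branch (Emax ~1.8 MeV)
Tl-209,2.162,min,Pb-209,1,beta_mean,0.28500,0.010,ENSDF-style beta branch
Tl-209,2.162,min,Pb-209,1,gamma,1.56710,0.998,ENSDF-style gamma line
Tl-209,2.162,min,Pb-209,1,gamma,0.46510,0.969,ENSDF-style gamma line
Tl-209,2.162,min,Pb-209,1,gamma,0.11720,0.845,ENSDF-style gamma line
Pb-209,3.234,h,Bi-209,1,beta_mean,0.19750,1.000,ENSDF-style beta branch (Emax 644 keV)
Bi-209,,,,,none,,,treated as stable terminal nuclide
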