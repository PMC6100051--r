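functional,basis,environment,state,energy_eV,osc_strength
PBE0,aug-cc-pVDZ,gas,1,3.57,0.28
PBE0,aug-cc-pVDZ,gas,2,3.81,0.000048
PBE0,aug-cc-pVDZ,gas,3,3.85,0.077
PBE0,aug-cc-pVDZ,gas,4,4.47,0.015
PBE0,aug-cc-pVDZ,gas,5,4.54,0.3
PBE0,aug-cc-pVTZ,gas,1,3.57,0.28
PBE0,aug-cc-pVTZ,gas,2,3.83,0.000058
PBE0,aug-cc-pVTZ,gas,3,3.86,0.072
PBE0,aug-cc-pVTZ,gas,4,4.49,0.015
PBE0,aug-cc-pVTZ,gas,5,4.54,0.31
B3LYP,aug-cc-pVDZ,gas,1,3.43,0.28
B3LYP,aug-cc-pVDZ,gas,2,3.71,0.00033
B3LYP,aug-cc-pVDZ,gas,3,3.73,0.00055
B3LYP,aug-cc-pVDZ,gas,4,4.22,0.013
B3LYP,aug-cc-pVDZ,gas,5,4.36,0.25
B3LYP,aug-cc-pVTZ,gas,1,3.44,0.28
B3LYP,aug-cc-pVTZ,gas,2,3.73,0.052
B3LYP,aug-cc-pVTZ,gas,3,3.74,0.00056
B3LYP,aug-cc-pVTZ,gas,4,4.23,0.013
B3LYP,aug-cc-pVTZ,gas,5,4.36,0.26
PBE0,cc-pVDZ,gas,1,3.64,0.26
PBE0,cc-pVDZ,gas,2,3.83,0.000021
PBE0,cc-pVDZ,gas,3,3.95,0.062
PBE0,cc-pVDZ,gas,4,4.65,0.36
PBE0,cc-pVDZ,gas,5,5.13,0.00014
PBE0,cc-pVTZ,gas,1,3.65,0.27
PBE0,cc-pVTZ,gas,2,3.86,0.000041
PBE0,cc-pVTZ,gas,3,3.94,0.073
PBE0,cc-pVTZ,gas,4,4.64,0.34
PBE0,cc-pVTZ,gas,5,5.15,0.00021
B3LYP,cc-pVDZ,gas,1,3.52,0.26
B3LYP,cc-pVDZ,gas,2,3.74,0.000015
B3LYP,cc-pVDZ,gas,3,3.82,0.045
B3LYP,cc-pVDZ,gas,4,4.48,0.31
B3LYP,cc-pVDZ,gas,5,4.88,0.000038
B3LYP,cc-pVTZ,gas,1,3.52,0.27
B3LYP,cc-pVTZ,gas,2,3.78,0.000035
B3LYP,cc-pVTZ,gas,3,3.81,0.052
B3LYP,cc-pVTZ,gas,4,4.46,0.29
B3LYP,cc-pVTZ,gas,5,4.91,0.000026
PBE0,aug-cc-pVDZ,water-COSMO,1,3.33,0.46
PBE0,aug-cc-pVDZ,water-COSMO,2,3.69,0.089
PBE0,aug-cc-pVDZ,water-COSMO,3,3.96,0.000054
PBE0,aug-cc-pVDZ,water-COSMO,4,4.32,0.21
PBE0,aug-cc-pVDZ,water-COSMO,5,4.67,0.016
PBE0,aug-cc-pVTZ,water-COSMO,1,3.34,0.45
PBE0,aug-cc-pVTZ,water-COSMO,2,3.70,0.089
PBE0,aug-cc-pVTZ,water-COSMO,3,3.98,0.000067
PBE0,aug-cc-pVTZ,water-COSMO,4,4.33,0.23
PBE0,aug-cc-pVTZ,water-COSMO,5,4.67,0.015
B3LYP,aug-cc-pVDZ,water-COSMO,1,3.19,0.45
B3LYP,aug-cc-pVDZ,water-COSMO,2,3.57,0.062
B3LYP,aug-cc-pVDZ,water-COSMO,3,3.88,0.000061
B3LYP,aug-cc-pVDZ,water-COSMO,4,4.12,0.18
B3LYP,aug-cc-pVDZ,water-COSMO,5,4.43,0.014
B3LYP,aug-cc-pVTZ,water-COSMO,1,3.21,0.44
B3LYP,aug-cc-pVTZ,water-COSMO,2,3.58,0.065
B3LYP,aug-cc-pVTZ,water-COSMO,3,3.92,0.000074
B3LYP,aug-cc-pVTZ,water-COSMO,4,4.15,0.20
B3LYP,aug-cc-pVTZ,water-COSMO,5,4.44,0.014
PBE0,cc-pVDZ,water-COSMO,1,3.44,0.37
PBE0,cc-pVDZ,water-COSMO,2,3.82,0.10
PBE0,cc-pVDZ,water-COSMO,3,3.98,0.000039
PBE0,cc-pVDZ,water-COSMO,4,4.47,0.29
PBE0,cc-pVDZ,water-COSMO,5,5.11,0.016
PBE0,cc-pVTZ,water-COSMO,1,3.44,0.41
PBE0,cc-pVTZ,water-COSMO,2,3.80,0.10
PBE0,cc-pVTZ,water-COSMO,3,4.04,0.000064
PBE0,cc-pVTZ,water-COSMO,4,4.44,0.27
PBE0,cc-pVTZ,water-COSMO,5,5.09,0.45
B3LYP,cc-pVDZ,water-COSMO,1,3.32,0.37
B3LYP,cc-pVDZ,water-COSMO,2,3.69,0.073
B3LYP,cc-pVDZ,water-COSMO,3,3.90,0.000034
B3LYP,cc-pVDZ,water-COSMO,4,4.28,0.24
B3LYP,cc-pVDZ,water-COSMO,5,4.95,0.27
B3LYP,cc-pVTZ,water-COSMO,1,3.31,0.41
B3LYP,cc-pVTZ,water-COSMO,2,3.68,0.074
B3LYP,cc-pVTZ,water-COSMO,3,3.97,0.000058
B3LYP,cc-pVTZ,water-COSMO,4,4.26,0.22
B3LYP,cc-pVTZ,water-COSMO,5,4.95,0.33
PBE0,aug-cc-pVDZ,cyclohexane-COSMO,1,3.46,0.39
PBE0,aug-cc-pVDZ,cyclohexane-COSMO,2,3.79,0.092
PBE0,aug-cc-pVDZ,cyclohexane-COSMO,3,3.86,0.000058
PBE0,aug-cc-pVDZ,cyclohexane-COSMO,4,4.44,0.32
PBE0,aug-cc-pVDZ,cyclohexane-COSMO,5,4.55,0.019
PBE0,aug-cc-pVTZ,cyclohexane-COSMO,1,3.47,0.39
PBE0,aug-cc-pVTZ,cyclohexane-COSMO,2,3.80,0.088
PBE0,aug-cc-pVTZ,cyclohexane-COSMO,3,3.88,0.000063
PBE0,aug-cc-pVTZ,cyclohexane-COSMO,4,4.44,0.34
PBE0,aug-cc-pVTZ,cyclohexane-COSMO,5,4.56,0.018
B3LYP,aug-cc-pVDZ,cyclohexane-COSMO,1,3.33,0.39
B3LYP,aug-cc-pVDZ,cyclohexane-COSMO,2,3.67,0.066
B3LYP,aug-cc-pVDZ,cyclohexane-COSMO,3,3.77,0.000052
B3LYP,aug-cc-pVDZ,cyclohexane-COSMO,4,4.26,0.27
B3LYP,aug-cc-pVDZ,cyclohexane-COSMO,5,4.30,0.016
B3LYP,aug-cc-pVTZ,cyclohexane-COSMO,1,3.34,0.39
B3LYP,aug-cc-pVTZ,cyclohexane-COSMO,2,3.67,0.063
B3LYP,aug-cc-pVTZ,cyclohexane-COSMO,3,3.79,0.000059
B3LYP,aug-cc-pVTZ,cyclohexane-COSMO,4,4.26,0.29
B3LYP,aug-cc-pVTZ,cyclohexane-COSMO,5,4.32,0.016
PBE0,cc-pVDZ,cyclohexane-COSMO,1,3.55,0.34
PBE0,cc-pVDZ,cyclohexane-COSMO,2,3.89,0.000033
PBE0,cc-pVDZ,cyclohexane-COSMO,3,3.90,0.082
PBE0,cc-pVDZ,cyclohexane-COSMO,4,4.56,0.40
PBE0,cc-pVDZ,cyclohexane-COSMO,5,5.15,0.37
PBE0,cc-pVTZ,cyclohexane-COSMO,1,3.55,0.36
PBE0,cc-pVTZ,cyclohexane-COSMO,2,3.89,0.091
PBE0,cc-pVTZ,cyclohexane-COSMO,3,3.902,0.00007
PBE0,cc-pVTZ,cyclohexane-COSMO,4,4.54,0.38
PBE0,cc-pVTZ,cyclohexane-COSMO,5,5.13,0.44
B3LYP,cc-pVDZ,cyclohexane-COSMO,1,3.43,0.34
B3LYP,cc-pVDZ,cyclohexane-COSMO,2,3.77,0.060
B3LYP,cc-pVDZ,cyclohexane-COSMO,3,3.79,0.000052
B3LYP,cc-pVDZ,cyclohexane-COSMO,4,4.38,0.34
B3LYP,cc-pVDZ,cyclohexane-COSMO,5,4.95,0.00029
B3LYP,cc-pVTZ,cyclohexane-COSMO,1,3.43,0.37
B3LYP,cc-pVTZ,cyclohexane-COSMO,2,3.77,0.066
B3LYP,cc-pVTZ,cyclohexane-COSMO,3,3.84,0.000052
B3LYP,cc-pVTZ,cyclohexane-COSMO,4,4.36,0.33
B3LYP,cc-pVTZ,cyclohexane-COSMO,5,4.98,0.33
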