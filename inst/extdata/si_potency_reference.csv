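particle,cell_line,LDH,ATP,CTB,beta_avg_printed
SiNP-12,A549,0.065,0.037,0.01,0.037
SiNP-15P,A549,0.04,0.033,0.015,0.029
SiNP-15C3,A549,0.01,0.018,0.018,0.015
SiNP-15C11,A549,0.053,0.008,0.008,0.023
SiNP-15NH2,A549,0.071,0.012,0.013,0.032
SiNP-15PEG,A549,0.002,0.021,0.01,0.011
SiNP-30P,A549,0.018,0.018,0.018,0.018
SiNP-30C3,A549,0.019,0.009,0.022,0.017
SiNP-30C11,A549,0.142,0.016,0.019,0.059
SiNP-30NH2,A549,0.083,0.051,0.046,0.06
SiNP-30PEG,A549,0.001,0.014,0.011,0.009
SiNP-50P,A549,0.021,0.01,0.013,0.015
SiNP-50C3,A549,0.057,0.016,0.005,0.026
SiNP-50C11,A549,0.108,0.01,0.006,0.041
SiNP-50NH2,A549,0.021,0.024,0.004,0.016
SiNP-50PEG,A549,0.007,0.004,0.004,0.005
SiNP-75P,A549,0.019,0.009,0.002,0.01
SiNP-75C3,A549,0.009,0.001,0.006,0.005
SiNP-75C11,A549,0.02,0.007,0.001,0.01
SiNP-75NH2,A549,0.032,0.006,0.005,0.014
SiNP-75PEG,A549,0.006,0.006,0.005,0.006
SiNP-100P,A549,0.032,0.015,0.001,0.016
SiNP-100C3,A549,0.007,0.006,0.009,0.007
SiNP-100C11,A549,0.014,0.001,0.008,0.008
SiNP-100NH2,A549,0.016,0.005,0.03,0.017
SiNP-100PEG,A549,0.0004,0.048,0.007,0.018
SiNP-12,J774A.1,0.355,0.36,0.263,0.326
SiNP-15P,J774A.1,0.068,0.027,0.006,0.034
SiNP-15C3,J774A.1,0.001,0.012,0.005,0.006
SiNP-15C11,J774A.1,0.011,0.024,0.009,0.015
SiNP-15NH2,J774A.1,0.016,0.011,0.016,0.014
SiNP-15PEG,J774A.1,0.001,0.026,0.001,0.009
SiNP-30P,J774A.1,0.05,0.012,0.001,0.021
SiNP-30C3,J774A.1,0.005,0.004,0.007,0.005
SiNP-30C11,J774A.1,0.027,0.015,0.003,0.015
SiNP-30NH2,J774A.1,0.06,0.008,0.012,0.027
SiNP-30PEG,J774A.1,0.004,0.0001,0.007,0.004
SiNP-50P,J774A.1,0.055,0.002,0.002,0.019
SiNP-50C3,J774A.1,0.021,0.019,0.01,0.016
SiNP-50C11,J774A.1,0.029,0.004,0.003,0.012
SiNP-50NH2,J774A.1,0.027,0.001,0.008,0.012
SiNP-50PEG,J774A.1,0,0.018,0.011,0.01
SiNP-75P,J774A.1,0.114,0.021,0.022,0.052
SiNP-75C3,J774A.1,0.01,0.006,0.012,0.009
SiNP-75C11,J774A.1,0.016,0.007,0.018,0.014
SiNP-75NH2,J774A.1,0.096,0.02,0.027,0.047
SiNP-75PEG,J774A.1,0.002,0.002,0.019,0.008
SiNP-100P,J774A.1,0.138,0.019,0.029,0.062
SiNP-100C3,J774A.1,0.003,0.009,0.013,0.008
SiNP-100C11,J774A.1,0.011,0.005,0.005,0.007
SiNP-100NH2,J774A.1,0.026,0.001,0.013,0.013
SiNP-100PEG,J774A.1,0.013,0.015,0.001,0.01
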