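particle,cell_line,beta_avg,rank
SiNP-12,A549,0.037,1
SiNP-15P,A549,0.029,3
SiNP-15C3,A549,0.015,6
SiNP-15C11,A549,0.023,4
SiNP-15NH2,A549,0.032,2
SiNP-15PEG,A549,0.011,7
SiNP-30P,A549,0.018,5
SiNP-75P,A549,0.01,8
SiNP-12,J774A.1,0.326,1
SiNP-15P,J774A.1,0.034,3
SiNP-15C3,J774A.1,0.006,8
SiNP-15C11,J774A.1,0.015,5
SiNP-15NH2,J774A.1,0.014,6
SiNP-15PEG,J774A.1,0.009,7
SiNP-30P,J774A.1,0.021,4
SiNP-75P,J774A.1,0.052,2
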