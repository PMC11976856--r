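particle,cell_line,beta_avg,rank
Ti-01,A549,0.031,3
Ti-02,A549,0.019,8
Ti-03,A549,0.025,4
Ti-04,A549,0.024,5
Ti-05,A549,0.024,5
Ti-06,A549,0.022,6
Ti-07,A549,0.02,7
Ti-08,A549,0.022,6
Ti-09,A549,0.02,7
Ti-10,A549,0.032,2
Ti-11,A549,0.038,1
TiO2,A549,0.031,3
Ti-01,J774A.1,0.018,4
Ti-02,J774A.1,0.009,10
Ti-03,J774A.1,0.014,6
Ti-04,J774A.1,0.024,3
Ti-05,J774A.1,0.013,7
Ti-06,J774A.1,0.015,5
Ti-07,J774A.1,0.015,5
Ti-08,J774A.1,0.032,1
Ti-09,J774A.1,0.013,7
Ti-10,J774A.1,0.012,8
Ti-11,J774A.1,0.028,2
TiO2,J774A.1,0.011,9
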