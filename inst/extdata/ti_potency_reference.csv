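particle,cell_line,LDH,ATP,CTB,beta_avg_printed
Ti-01,A549,0.0413,0.0172,0.0348,0.0311
Ti-02,A549,0.0194,0.0075,0.0298,0.0189
Ti-03,A549,0.0212,0.0206,0.0327,0.0248
Ti-04,A549,0.0294,0.0094,0.0337,0.0242
Ti-05,A549,0.0342,0.0051,0.0318,0.0237
Ti-06,A549,0.0379,0.0045,0.0228,0.0217
Ti-07,A549,0.0331,0.0017,0.0260,0.0203
Ti-08,A549,0.0348,0.0057,0.0250,0.0218
Ti-09,A549,0.0349,0.0141,0.0114,0.0201
Ti-10,A549,0.0396,0.0269,0.0295,0.0320
Ti-11,A549,0.0569,0.0348,0.0235,0.0384
TiO2,A549,0.0380,0.0268,0.0285,0.0311
Ti-01,J774A.1,0.0319,0.0095,0.0117,0.0177
Ti-02,J774A.1,0.0051,0.0052,0.0156,0.0086
Ti-03,J774A.1,0.0143,0.0131,0.0157,0.0144
Ti-04,J774A.1,0.0422,0.0200,0.0107,0.0243
Ti-05,J774A.1,0.0074,0.0205,0.0104,0.0128
Ti-06,J774A.1,0.0210,0.0163,0.0066,0.0147
Ti-07,J774A.1,0.0190,0.0133,0.0135,0.0153
Ti-08,J774A.1,0.0424,0.0192,0.0337,0.0318
Ti-09,J774A.1,0.0041,0.0177,0.0166,0.0128
Ti-10,J774A.1,0.0022,0.0140,0.0183,0.0115
Ti-11,J774A.1,0.0546,0.0196,0.0101,0.0281
TiO2,J774A.1,0.0079,0.0218,0.0033,0.0110
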