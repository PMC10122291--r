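# Published study-level hazard ratios (95% CI) for first VT recurrence:
# MARTHA ambispective analysis and MEGA prospective analysis, one row per
# covariate / ABO haplotype (O1 reference). Inputs for meta_fixed().
study,variable,hr,lo,hi
MARTHA_ambispective,sex,1.65,1.36,2.01
MEGA,sex,1.81,1.46,2.25
MARTHA_ambispective,age10,1.08,1.02,1.15
MEGA,age10,0.99,0.92,1.07
MARTHA_ambispective,dvt,1.17,0.96,1.42
MEGA,dvt,1.15,0.95,1.40
MARTHA_ambispective,provoked,0.99,0.80,1.23
MEGA,provoked,0.61,0.49,0.76
MARTHA_ambispective,A1,1.15,1.00,1.32
MEGA,A1,1.21,1.03,1.42
MARTHA_ambispective,A2,1.27,0.98,1.64
MEGA,A2,1.11,0.86,1.43
MARTHA_ambispective,B,1.02,0.82,1.27
MEGA,B,1.00,0.78,1.29
MARTHA_ambispective,O2,1.19,0.73,1.94
MEGA,O2,0.86,0.50,1.49
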