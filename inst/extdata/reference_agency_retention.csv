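agency,avg_retention_pct,io_proportion_pct,applied_avg_pct
HHS/CDC,86.33,26.75,89.99
Dept of Labor,99.17,0,99.17
Dept of Defense,93.97,76.36,98.57
Bur. PRM,93.65,0.00,93.65
HHS/HRSA,68.51,40.90,81.39
USAID,89.06,28.29,92.16
All Others,NA,NA,87.41
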