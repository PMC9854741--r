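ruleset,condition,observation_rate,aggregation_window,W_AP,patient_rate,alarm_rate,alarm_rate_sd,EDT_median,EDT_IQR
A1,VS_12,VS_12,AW_0,235,64.47,0.33,0.56,0,0
A1,VS_4,VS_4,AW_0,683,85.53,0.96,1.37,0,0
A1,VS_1,VS_1,AW_0,1364,94.74,1.93,1.83,3,2.00
A1,VS_15,VS_15,AW_0,1899,98.68,2.68,1.99,3.25,1.75
A1,VS_SD,VS_SD,-,2251,100,3.18,2.02,3.5,1.52
A1,AW_15,VS_OD,AW_15,1759,96.05,2.48,2.02,3.41,1.76
A1,AW_1,VS_OD,AW_1,1195,76.32,1.69,1.88,3.67,1.68
A1,AW_4,VS_OD,AW_4,791,65.79,1.12,1.65,3.97,1.45
A2,VS_12,VS_12,AW_0,609,93.42,0.86,0.76,0,0
A2,VS_4,VS_4,AW_0,1737,96.05,2.45,1.89,0,0
A2,VS_1,VS_1,AW_0,2548,98.68,3.60,1.92,3,1.00
A2,VS_15,VS_15,AW_0,2922,100,4.13,1.78,3.75,0.75
A2,VS_SD,VS_SD,-,3113,100,4.40,1.68,3.96,0.55
A2,AW_15,VS_OD,AW_15,2855,100,4.03,1.83,3.98,0.74
A2,AW_1,VS_OD,AW_1,2467,98.68,3.48,2.04,4.00,0.79
A2,AW_4,VS_OD,AW_4,2121,93.42,3.00,2.22,4.00,0.28
A3,VS_12,VS_12,AW_0,65,30.26,0.09,0.31,0,0
A3,VS_4,VS_4,AW_0,185,50.00,0.26,0.71,0,0
A3,VS_1,VS_1,AW_0,435,61.84,0.61,1.16,2.00,2.00
A3,VS_15,VS_15,AW_0,712,65.79,1.01,1.50,2.75,2.00
A3,VS_SD,VS_SD,-,942,80.26,1.33,1.66,3.05,2.05
A3,AW_15,VS_OD,AW_15,626,65.79,0.88,1.45,3.04,2.16
A3,AW_1,VS_OD,AW_1,356,48.68,0.50,1.13,3.25,2.16
A3,AW_4,VS_OD,AW_4,200,32.89,0.28,0.88,3.84,1.90
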