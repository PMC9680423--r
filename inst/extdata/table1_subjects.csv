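subject,exp_threshold,exp_threshold_sd,sim_threshold,sim_threshold_sd,exp_slope,exp_slope_sd,sim_slope,sim_slope_sd,k,tau,delta,note
C12,4.041,1.05,5.209,0.200,0.261,0.03,0.260,0.0048,4,0.0245,0.022,
A10,4.176,1.08,,,0.252,0.028,,,,,,
B04,4.506,1.1,,,0.246,0.027,,,,,,
B01,4.805,1.12,,,0.243,0.026,,,,,,
A15,5.321,1.14,5.448,0.205,0.242,0.025,0.251,0.0047,2,0.033,0.032,
B05,5.361,1.04,5.425,0.193,0.284,0.028,0.279,0.005,4,0.037,0.03,
B09,6.602,1.41,6.871,0.268,0.188,0.02,0.181,0.0036,4,0.025,0.034,
A11,6.637,1.52,,,0.171,0.019,,,,,,
A06,6.609,1.21,6.556,0.232,0.233,0.022,0.218,0.004,8,0.033,0.032,
A01,7.000,1.51,7.228,0.263,0.175,0.019,0.188,0.0036,8,0.03,0.034,
C07,7.097,1.42,,,0.192,0.02,,,,,,
C11,7.165,1.39,,,0.197,0.02,,,,,,
B14,7.692,1.79,7.664,0.363,0.147,0.017,0.130,0.0031,1,0.024,0.026,
B08,7.753,1.8,,,0.146,0.017,,,,,,
A02,7.837,1.86,,,0.141,0.017,,,,,,
A13,7.873,1.69,,,0.159,0.018,,,,,,
B11,8.132,2,8.509,0.421,0.132,0.017,0.115,0.003,1,0.024,0.028,
C13,8.594,2.08,,,0.128,0.016,,,,,,
C04,9.173,1.77,9.275,0.337,0.158,0.017,0.151,0.003,16,0.025,0.034,
B03,9.191,2.64,9.198,0.438,0.103,0.016,0.113,0.0029,2,0.024,0.028,
C06,9.543,2.34,9.818,0.496,0.118,0.016,0.102,0.0028,2,0.024,0.03,
B07,9.589,2.86,,,0.096,0.015,,,,,,
C08,9.747,1.69,9.791,0.313,0.170,0.017,0.168,0.0031,32,0.033,0.032,
A03,10.49,1.56,11.131,0.376,0.130,0.011,0.144,0.0028,32,0.025,0.34,suspected_typo_delta_0.034
A04,10.801,2.2,,,0.132,0.015,,,,,,
A07,10.843,2.25,,,0.128,0.015,,,,,,
A05,10.77,2.71,10.696,0.529,0.105,0.015,0.098,0.0028,4,0.024,0.028,
C01,10.83,2.6,,,0.110,0.015,,,,,,
A08,12.132,2.75,12.315,0.606,0.109,0.015,0.091,0.0027,8,0.024,0.028,
B02,12.173,2.67,,,0.113,0.015,,,,,,
B06,12.525,2.81,,,0.108,0.014,,,,,,
B13,12.86,3.93,12.258,0.664,0.078,0.014,0.083,0.0027,2,0.024,0.034,
A14,16.617,4.88,17.978,1.105,0.071,0.013,0.06,0.0025,8,0.024,0.036,
A09,17.194,5.84,,,0.061,0.013,,,,,,
C02,17.787,5.35,,,0.068,0.013,,,,,,
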