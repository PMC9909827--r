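patient_id,tissue,ground_truth_cm3,predicted_cm3
1,subq,4461.47,4522.96
2,subq,5415.30,5421.10
4,subq,3620.08,3639.34
5,subq,4264.22,4198.49
6,subq,2461.13,2473.48
7,subq,3353.95,3334.67
8,subq,3704.44,3702.73
1,visceral,3242.54,3251.60
2,visceral,2611.58,2597.90
4,visceral,3208.96,3254.98
5,visceral,3041.52,3019.03
6,visceral,772.35,789.36
7,visceral,2411.30,2356.63
8,visceral,865.74,861.71
1,muscle,2317.96,2464.54
2,muscle,2521.99,2522.15
4,muscle,1718.25,1841.16
5,muscle,2185.81,2330.26
6,muscle,1653.20,1720.89
7,muscle,2233.17,2369.07
8,muscle,1733.22,1817.44
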