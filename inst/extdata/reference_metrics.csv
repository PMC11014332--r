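taxonomy,class,precision,recall,f1
T1_sedentary,sedentary,0.92,0.82,0.87
T1_sedentary,active,0.84,0.93,0.88
T2_activity_type,sedentary,0.65,0.89,0.75
T2_activity_type,mixed_movement,0.53,0.52,0.53
T2_activity_type,walking,0.34,0.56,0.42
T2_activity_type,running,0.99,0.56,0.72
T3_intensity,sedentary,0.90,0.72,0.80
T3_intensity,light,0.11,0.74,0.20
T3_intensity,moderate,0.92,0.63,0.75
T3_intensity,vigorous,0.43,0.27,0.33
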