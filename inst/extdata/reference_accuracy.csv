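taxonomy,accuracy_pct
T1_sedentary,87.4
T2_activity_type,63.1
T3_intensity,68.6
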