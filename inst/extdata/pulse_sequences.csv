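sequence,peak_voltage_V,pulse_duration_us,repetition_frequency_Hz,pulse_count
1,500,100,4762,8
2,500,100,1,8
3,500,1000,1,8
4,750,100,4762,8
5,750,100,1,8
6,750,1000,1,8
7,1000,100,4762,8
8,1000,100,1,8
9,1000,1000,1,8
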