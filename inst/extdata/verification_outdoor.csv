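size_class,object_id,measured_mm,predicted_mm,error_mm,error_rate_pct
small,4,25.17,20.67,4.50,17.88
small,19,29.76,27.41,2.35,7.90
small,20,27.31,23.47,3.84,14.06
small,24,27.64,25.92,1.72,6.22
small,27,30.44,27.33,3.11,10.22
medium,1,25.58,26.44,0.86,3.36
medium,2,22.40,20.32,2.08,9.29
medium,3,27.55,23.30,4.25,15.43
medium,5,28.02,24.38,3.64,13.00
medium,12,29.28,30.91,1.63,5.57
medium,14,24.20,23.95,0.25,1.03
medium,15,27.00,24.04,2.96,10.96
medium,16,27.27,25.45,1.82,6.67
medium,17,29.07,26.65,2.42,8.32
medium,26,27.61,27.40,0.21,0.76
large,6,31.40,28.15,3.25,10.35
large,7,31.62,31.86,0.24,0.76
large,8,28.28,27.07,1.21,4.28
large,9,31.75,27.57,4.18,13.17
large,10,25.64,26.35,0.71,2.77
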