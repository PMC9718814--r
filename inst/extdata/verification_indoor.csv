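size_class,object_id,measured_mm,predicted_mm,error_mm,error_rate_pct
small,11,33.64,31.57,2.07,6.15
medium,1,35.26,33.95,1.31,3.72
medium,2,36.73,32.63,4.10,11.16
medium,3,34.23,35.14,0.91,2.66
medium,4,34.82,36.07,1.25,3.59
medium,5,36.03,36.48,0.45,1.25
medium,7,33.94,29.85,4.09,12.05
medium,8,35.03,33.45,1.58,4.51
medium,9,34.77,34.80,0.03,0.09
medium,13,34.73,35.34,0.61,1.76
medium,17,35.78,32.69,3.09,8.64
medium,18,34.02,37.33,3.31,9.73
medium,19,34.97,35.09,0.12,0.34
medium,20,34.96,33.60,1.36,3.89
medium,21,35.47,34.49,0.98,2.76
medium,22,34.55,27.03,7.52,21.77
medium,25,33.66,34.08,0.42,1.25
medium,26,34.83,36.43,1.60,4.59
medium,27,35.58,38.50,2.92,8.21
medium,29,34.52,37.99,3.47,10.05
large,14,33.35,36.02,2.67,8.01
large,15,35.66,37.66,2.00,5.61
large,16,35.47,34.87,0.60,1.69
large,23,34.60,36.14,1.54,4.45
large,24,37.32,35.45,1.87,5.01
large,30,34.05,37.17,3.12,9.16
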