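age,factor,mean,sd
25,radius,1.00,0.06
25,thickness,1.00,0.18
25,stiffness,1.00,0.16
25,resistance,1.00,0.22
25,compliance,1.00,0.27
25,cardiac_output,1.00,0.23
35,radius,1.03,0.06
35,thickness,1.10,0.20
35,stiffness,1.08,0.16
35,resistance,1.04,0.23
35,compliance,0.88,0.22
35,cardiac_output,0.95,0.22
45,radius,1.04,0.07
45,thickness,1.12,0.22
45,stiffness,1.23,0.16
45,resistance,1.10,0.25
45,compliance,0.77,0.21
45,cardiac_output,0.90,0.22
55,radius,1.07,0.07
55,thickness,1.25,0.24
55,stiffness,1.29,0.26
55,resistance,1.21,0.27
55,compliance,0.65,0.18
55,cardiac_output,0.86,0.21
65,radius,1.13,0.07
65,thickness,1.52,0.26
65,stiffness,1.63,0.35
65,resistance,1.23,0.28
65,compliance,0.54,0.15
65,cardiac_output,0.80,0.20
75,radius,1.16,0.07
75,thickness,1.75,0.28
75,stiffness,2.00,0.45
75,resistance,1.46,0.29
75,compliance,0.42,0.12
75,cardiac_output,0.75,0.17
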