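gene,timepoint_h,ir_no_cleavage,ir_cleavage,printed_difference_pct
gyrA,0,0.83,0.94,14
gyrA,1,1.33,1.11,-17
gyrA,2,1.21,1.14,-6
gyrA,3,0.84,1.04,25
samT,0,0.96,1.14,18
samT,1,3.69,4.67,26
samT,2,14.93,17.44,17
samT,3,9.24,9.75,5
metIC,0,1.07,1.21,13
metIC,1,1.02,1.43,40
metIC,2,17.38,25.91,49
metIC,3,1.07,1.25,17
metE,0,1.08,1.21,11
metE,1,5.72,7.60,33
metE,2,37.21,44.66,20
metE,3,18.79,30.02,60
mtnKA,0,0.98,0.92,-6
mtnKA,1,2.01,2.35,17
mtnKA,2,1.05,1.27,21
mtnKA,3,0.40,0.50,27
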