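term,value
prev_2,1.305
prev_3,0.84
prev_4,2.581
prev_5,1.253
prev_6,4.504
prev_7,3.617
prev_8,4.213
prev_9,6.072
years_2,0.293
years_3plus,0.315
d_moderate,-0.15
d_marked,0.873
d_severe,1.349
not_splenectomized,-1.089
cutpoint_1,0.74
cutpoint_2,1.662
cutpoint_3,1.727
cutpoint_4,5.054
cutpoint_5,5.835
cutpoint_6,6.577
cutpoint_7,8.808
cutpoint_8,9.066
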