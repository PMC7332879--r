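element,mass_number,mass,abundance
H,1,1.007825,0.999885
H,2,2.014102,0.000115
C,12,12,0.9893
C,13,13.003355,0.0107
N,14,14.003074,0.99636
N,15,15.000109,0.00364
O,16,15.994915,0.99757
O,17,16.999132,0.00038
O,18,17.99916,0.00205
Na,23,22.989769,1
P,31,30.973762,1
S,32,31.972071,0.9499
S,33,32.971459,0.0075
S,34,33.967867,0.0425
S,36,35.967081,1e-04
K,39,38.963706,0.932581
K,40,39.963998,0.000117
K,41,40.961825,0.067302
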