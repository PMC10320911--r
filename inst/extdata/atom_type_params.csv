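pair_type,vdw_radius,lj_epsilon,solv_par
C,1.9,0.150,-0.00143
A,1.9,0.150,-0.00052
N,1.8,0.160,-0.00162
NA,1.8,0.160,-0.00162
O,1.7,0.200,-0.00251
OA,1.7,0.200,-0.00251
S,2.0,0.200,-0.00214
SA,2.0,0.200,-0.00214
P,2.1,0.200,-0.00110
F,1.5,0.080,-0.00110
Cl,1.8,0.276,-0.00110
Br,2.0,0.389,-0.00110
I,2.2,0.550,-0.00110
HD,1.0,0.020,0.00051
H,1.1,0.020,0.00051
MET,1.2,0.875,-0.00110
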