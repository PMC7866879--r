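variant,sequence,structure,pka,dynamics,substrate_zn,active_site,overall,role
H1146A,damaging,benign,damaging,damaging,damaging,damaging,damaging,damaging_control
E1148A,damaging,damaging,damaging,damaging,damaging,damaging,damaging,damaging_control
H1060L,benign,benign,benign,benign,benign,benign,benign,benign_control
S912N,benign,benign,benign,benign,benign,benign,benign,benign_control
T1323A,benign,benign,benign,benign,benign,benign,benign,benign_control
N910S,benign,damaging,benign,damaging,benign,VUS,damaging,query
D980V,damaging,VUS,VUS,damaging,benign,damaging,damaging,query
S1025G,damaging,VUS,benign,damaging,damaging,VUS,damaging,query
C1153R,damaging,damaging,damaging,damaging,damaging,damaging,damaging,query
C1153Y,damaging,damaging,damaging,damaging,damaging,VUS,damaging,query
P1195L,VUS,damaging,damaging,damaging,damaging,VUS,damaging,query
L1200F,damaging,damaging,damaging,damaging,benign,benign,damaging,query
Q1212R,damaging,damaging,damaging,damaging,damaging,VUS,damaging,query
Q1248R,damaging,damaging,damaging,damaging,damaging,VUS,damaging,query
R1255W,damaging,damaging,damaging,damaging,damaging,damaging,damaging,query
R1351Q,benign,damaging,damaging,damaging,damaging,VUS,damaging,query
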