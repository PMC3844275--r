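a: 1.98351
p: 0.159051
q: 0.0309806
m: 17.381499999999999
r: 0.800823
s: 0.0557808
T0: 223.11099999999999
TP: 254.0
OT: 0.0
L0: 0.7178
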