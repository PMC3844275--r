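a: 1.8001
p: 0.0846
q: 0.0641
m: 1.048
r: 0.1501
s: 0.0178
T0: 223.0
TP: 252.0
OT: 0.0
L0: 0.7178
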