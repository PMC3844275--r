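a: 1.98351
p: 0.218373
q: 0.0321599
m: 424.194000000000017
r: 0.234962
s: 0.234962
T0: 223.182999999999993
TP: 254.0
OT: 2.52521
L0: 1.4655
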