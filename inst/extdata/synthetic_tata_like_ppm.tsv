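nt	1	2	3	4	5	6
A	0.10	0.90	0.09	0.90	0.75	0.55
C	0.04	0.03	0.03	0.03	0.05	0.08
G	0.04	0.03	0.03	0.03	0.05	0.12
T	0.82	0.04	0.85	0.04	0.15	0.25
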