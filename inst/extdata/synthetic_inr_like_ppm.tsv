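nt	1	2	3	4	5	6
A	0.05	0.14	0.90	0.08	0.10	0.08
C	0.05	0.70	0.04	0.07	0.08	0.40
G	0.05	0.08	0.03	0.75	0.12	0.07
T	0.85	0.08	0.03	0.10	0.70	0.45
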