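prom_001	47	53
prom_002	47	53
prom_003	47	53
prom_004	47	53
prom_005	47	53
prom_006	47	53
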