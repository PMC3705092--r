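analysis	hr	ci_low	ci_high
discovery	0.92	0.88	0.97
replication_pooled	0.97	0.93	1.00
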