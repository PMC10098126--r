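nationality	sex	side	age_min	age_max	mean_deg	sd_deg
chinese	female	either	0.4	8.0	23	4
chinese	male	either	0.4	8.0	23	4
other	female	either	0.4	8.0	23	4
other	male	either	0.4	8.0	23	4
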