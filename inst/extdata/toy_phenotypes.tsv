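sample	SBP	DBP	AGE	SEX
S1	121.5	79.2	44	1
S2	135.0	88.1	51	0
S3	118.2	NA	38	1
S4	142.7	91.0	60	0
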