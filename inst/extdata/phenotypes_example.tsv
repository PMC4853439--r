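subject_id	pr_ms	rr_ms	qrs_ms	qt_ms
s1	212	880	96	401
s2	161	905	92	388
s3	158		90	395
s4	205	940	99	410
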