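subject_id	group	genotype
s1	case	T/C
s2	case	T/T
s3	control_longlived	T/T
s4	control_healthy	C/T
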