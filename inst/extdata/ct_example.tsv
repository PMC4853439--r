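sample_id	assay_id	role	ct1	ct2	ct3
s1	sim-miR-target	target	30.1	30.2	30.0
s1	sim-spike-in	spike_in	20.0	20.1	19.9
s2	sim-miR-target	target	28.4	28.5	38.0
s2	sim-spike-in	spike_in	20.2	20.0	20.1
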