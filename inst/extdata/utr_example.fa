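>sim-utr synthetic 3'UTR; window 5-10 pairs the sim-miR-0001 seed
AAAATAAGCTAAAA
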