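>sim-miR-0001 synthetic example mature miRNA
UAGCUUAUCAGACUGAUGUUGA
>sim-miR-0002 synthetic example mature miRNA
AGGGACGGCAUCAGUCCGAUAC
>mmu-sim-0003 synthetic non-human-prefixed record
ACGUACGUACGUACGUACGUAC
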