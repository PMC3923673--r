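contig	start	length
c1	0	20
c2	20	10
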