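param	value
duplex_initiation	4.09
terminal_au_penalty	0.45
bulge_base	3.80
bulge_ext	0.60
internal_base	1.70
internal_ext	0.50
internal_asym	0.50
max_loop	10
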