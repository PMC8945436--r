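param	value
stack:AA/UU	-0.93
stack:AU/UA	-1.10
stack:UA/AU	-1.33
stack:CU/GA	-2.08
stack:CA/GU	-2.11
stack:GU/CA	-2.24
stack:GA/CU	-2.35
stack:CG/GC	-2.36
stack:GG/CC	-3.26
stack:GC/CG	-3.42
wobble_stack	-1.00
bulge_open	3.80
bulge_ext	0.50
iloop_open	4.00
iloop_ext	0.50
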