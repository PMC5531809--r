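#flow_order=TACG
frame_example	0.03	1.03	0.09	0.12	1.89	0.09	0.09	1.01
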