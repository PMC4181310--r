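species	model	label	intercept	slope
white-tailed deer	Haugen and Speake	HS	0.66	2.20
white-tailed deer	Sams	S	-8.29	3.66
white-tailed deer	Brinkman	B	-5.73	3.14
white-tailed deer	Haskell	H	0.57	3.87
mule deer	Robinette	R	-6.30	2.55
mule deer	Haskell	H	5.29	2.54
pronghorn	Tucker and Garner	TG	0.89	2.34
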