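Orthogroup	GenA	GenB	GenC	GenD
OG0001	gA1, gA2	gB1		
OG0002	gA3		gC1	
OG0003		gB2, gB3	gC2	gD1
OG0004	gA4	gB4		
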