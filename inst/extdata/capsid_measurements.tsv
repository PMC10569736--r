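phage_id	diameter_nm	diameter_sd_nm	tail_nm	genome_bp
Bc01	94	3	34	100841
Bc03	97	3	33	99523
Bc11	90	4	25	90575
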