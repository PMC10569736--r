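genome_id	host_id
GenA	HostX
GenB	HostX
GenC	HostY
GenD	HostY
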