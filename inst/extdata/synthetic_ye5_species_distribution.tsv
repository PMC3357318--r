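distribution	count
shared_hominidae_and_siamang	25
shared_hominidae	38
shared_homininae	39
shared_human_chimp	8
human_specific	8
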