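helix: helix
strand: strand
coil: coil
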