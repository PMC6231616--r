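732	Abdomen; Lower abdomen; Lower middle quadrant
213	Cranium; Facial cranium; Nose area
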