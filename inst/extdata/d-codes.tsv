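125	Coronal; Anteroposterior; Upright
127	Coronal; Anteroposterior; Supine
228	Sagital; Lateral, left-right; Inclination
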