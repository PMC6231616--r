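443	Gastrointestinal system; Small intestine; Ileum
512	Uropoietic system; Kidney; Renal pelvis
500	Uropoietic system
625	Reproductive female system; Breast
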