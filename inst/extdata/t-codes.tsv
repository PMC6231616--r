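1124	Xray; Plain Radiology; Analog; Low Beam Energy
1123	Xray; Plain Radiology; Analog; High Beam Energy
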