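smartphone,device_correct,device_incorrect
correct,1065,95
incorrect,61,33
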