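model,device_wer_pct,smartphone_wer_pct
greedy,5.75,3.58
beam,5.80,3.63
beam_lm,4.16,2.73
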