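original,pred_1,pred_2,pred_3
1,62,2,3
2,0,52,3
3,0,2,40
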