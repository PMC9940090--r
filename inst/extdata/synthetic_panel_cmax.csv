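drug,cmax_nM
synthA_herg,2
synthB_multi,100
synthC_cal,120
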