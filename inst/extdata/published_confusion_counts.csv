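model,tp,fn,tn,fp
dCDT dual task,95,13,82,17
sRCFT delayed recall,93,15,90,9
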