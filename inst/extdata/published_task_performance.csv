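model,type,accuracy,sensitivity,specificity,auc,auc_lo,auc_hi
dCDT single task,drawing,0.845,0.861,0.828,0.904,0.846,0.962
dCDT dual task,drawing,0.855,0.880,0.828,0.892,0.830,0.954
sRCFT raw copy,drawing,0.816,0.843,0.788,0.885,0.820,0.950
sRCFT delayed recall,drawing,0.884,0.861,0.909,0.945,0.903,0.986
clock drag and drop,dragging,0.845,0.861,0.828,0.904,0.846,0.962
sRCFT point and line,dragging,0.855,0.861,0.848,0.912,0.859,0.965
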