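"assay","reference","TP","FP","TN","FN"
"SCM","WB",21,8,34,1
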