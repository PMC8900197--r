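"assay","reference","TP","FP","TN","FN"
"SCM","total",43,20,81,4
"BF","total",41,39,62,6
"SCM","ICM",27,9,51,2
"BF","ICM",25,24,36,4
"SCM","WB",16,11,30,2
"BF","WB",16,15,26,2
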