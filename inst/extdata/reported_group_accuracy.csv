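model,head,balance,tail
expert-head,98.33,NA,NA
expert-balance,NA,94.01,NA
expert-tail,NA,NA,91.46
expert-ensemble,93.31,94.32,92.68
msc-mobilevit,95.32,91.17,79.27
msc-mobilevit-distillation,97.32,94.32,93.83
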