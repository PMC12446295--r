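model,accuracy,precision,recall,f1
expert-head,98.09,98.14,98.11,98.13
expert-balance,94.48,90.26,94.28,92.09
expert-tail,95.99,75.17,90.29,80.53
expert-ensemble,93.58,86.69,92.55,88.64
msc-mobilevit,92.68,86.29,85.01,85.19
msc-mobilevit-distillation,95.99,91.03,93.57,92.02
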