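fold,model,accuracy,precision,recall,f1
K1,baseline,94.29,88.69,85.84,86.83
K2,baseline,94.28,89.91,89.05,89.11
K3,baseline,94.76,87.17,82.50,83.90
K4,baseline,95.23,89.60,87.97,89.12
K5,baseline,94.43,85.51,83.21,83.21
K1,ours,96.03,93.81,91.21,92.34
K2,ours,95.88,91.45,91.70,90.49
K3,ours,95.71,89.46,93.70,91.00
K4,ours,97.24,90.69,94.02,91.78
K5,ours,95.44,90.63,92.10,91.06
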