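class,group,recall
Idle Period,Head,99.34
Mid Production,Head,95.24
Late Production,Balance,93.13
Seedling Pulling,Balance,94.62
Planting,Balance,96.43
Substrate Placement,Tail,96.55
Hole Opening,Tail,96.00
Substrate Soaking,Tail,87.50
Early Production,Tail,83.33
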