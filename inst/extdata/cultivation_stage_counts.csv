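class,raw,train,train_aug,test
Idle Period,608,304,304,304
Substrate Placement,59,30,90,29
Hole Opening,51,26,104,25
Substrate Soaking,32,16,96,16
Planting,113,57,114,56
Early Production,24,12,96,12
Mid Production,589,295,295,294
Late Production,263,132,132,131
Seedling Pulling,260,130,130,130
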