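category,statement,c1,c2,c3,c4,c5
Accuracy,The simulation of the procedure was realistic,0,0,1,2,1
Accuracy,The accuracy of the needle placement was adequate,0,0,1,2,1
Accuracy,The haptic feedback from the gelatin phantom was realistic,0,0,0,4,0
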