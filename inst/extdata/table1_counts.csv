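category,statement,c1,c2,c3,c4,c5
Acceptability,I enjoyed this training method,0,0,0,3,13
Acceptability,The application was easy to use,0,3,8,4,1
Acceptability,I will train and study differently when I know I will be assessed with the HoloLens,1,2,4,6,3
Acceptability,I feel more confident about my skills after a HoloLens training,0,2,2,7,5
Acceptability,The HoloLens hindered me to perform the Biopsy procedure,5,4,5,2,0
Acceptability,This HoloLens app is a good addition to my current training,0,2,1,2,11
Accuracy,The simulation of the procedure was realistic,1,0,4,9,2
Accuracy,The accuracy of the needle placement was adequate,0,4,1,8,3
Accuracy,The haptic feedback from the gelatin phantom was realistic,0,1,4,11,0
Feasibility,I could demonstrate my skills effectively,0,4,6,5,1
Feasibility,I experienced discomfort wearing the HoloLens,11,3,2,0,0
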