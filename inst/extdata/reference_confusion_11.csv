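"true_label","Home/Standing","Home/Walking","Home/Sitting","Office/Standing","Office/Walking","Office/Sitting","Outdoor/Standing","Outdoor/Walking","Outdoor/Sitting","Outdoor/Jogging","Riding a car"
"Home/Standing",90.32,0,9.68,0,0,0,0,0,0,0,0
"Home/Walking",10.43,83.47,6.1,0,0,0,0,0,0,0,0
"Home/Sitting",2.56,0,98.44,0,0,0,0,0,0,0,0
"Office/Standing",0,0,0,95.2,0,4.8,0,0,0,0,0
"Office/Walking",0,0,0,4.84,94.35,0.81,0,0,0,0,0
"Office/Sitting",0,0,0,1.2,0.61,98.19,0,0,0,0,0
"Outdoor/Standing",0,0,0,0,0,0,94.34,0,5.66,0,0
"Outdoor/Walking",0,0,0,0,0,0,12.77,80.85,6.38,0,0
"Outdoor/Sitting",0,0,0,0,0,0,2.5,0,97.5,0,0
"Outdoor/Jogging",0,0,0,0,0,0,2.17,10.86,1.47,85.5,0
"Riding a car",0,0,0,0,0,0,16.25,6.25,1.25,0,76.25
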