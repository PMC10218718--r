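model,class,precision,recall,f1
SETUP2/GoogLeNet,other,0.97,0.90,0.93
SETUP2/GoogLeNet,stroma,0.91,0.97,0.94
SETUP2/GoogLeNet,tumor,0.99,0.99,0.99
SETUP2/ResNet50,other,0.97,0.92,0.94
SETUP2/ResNet50,stroma,0.93,0.97,0.95
SETUP2/ResNet50,tumor,0.99,0.99,0.99
SETUP2/VGG19,other,0.95,0.93,0.94
SETUP2/VGG19,stroma,0.94,0.95,0.94
SETUP2/VGG19,tumor,0.98,0.99,0.99
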