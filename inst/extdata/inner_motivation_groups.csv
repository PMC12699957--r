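label,n,mean,sd
control,15,26.06,1.87
kinect,15,35.13,3.20
monocular,15,34.00,4.41
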