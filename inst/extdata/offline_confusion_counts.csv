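location,land,tp,fp,fn,tn
L1,cropland,74,21,16,79
L2,cropland,38,11,18,31
L3,cropland,56,0,31,25
L1,orchard,35,9,13,31
L2,orchard,41,2,10,33
L3,orchard,37,18,15,40
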