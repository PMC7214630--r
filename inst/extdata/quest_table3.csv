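item,mean,sd
Adjustments,1.7,0.7
Dimensions,2.7,0.9
Comfort,3,1.2
Durability,3.1,1.1
Weight,3.3,1.2
Effectiveness,3.3,1
Safety,3.4,1.1
Ease of use,4.3,1.1
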