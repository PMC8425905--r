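phantom_ref,a,b
body-32cm,3.704369,0.03671937
head-16cm,1.874799,0.03871313
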