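scale,education,age,printed,note
fab2,21,70,-0.16,row prints 12 values for 13 ages with non-monotone run -0.14/-0.16/0.34; formula gives 0.00
fab2,21,75,,cell not resolvable in print; formula gives 0.16
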