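class,HC,LHL,RHL
HC,194,4,2
LHL,6,141,3
RHL,4,5,131
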