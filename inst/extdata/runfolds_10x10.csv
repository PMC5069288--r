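run,F1,F2,F3,F4,F5,F6,F7,F8,F9,F10,T1,T2,T3,T4,T5,T6,T7,T8,T9,T10
1,3,5,5,4,5,5,5,5,5,5,4,5,5,5,5,5,5,5,5,5
2,3,5,5,5,5,5,5,5,5,5,4,5,5,5,5,5,5,5,5,5
3,4,5,5,5,5,5,5,5,5,4,4,5,5,5,5,5,5,5,5,5
4,4,5,5,5,5,5,5,3,5,5,4,5,5,5,5,5,5,5,5,5
5,4,5,5,5,5,4,5,5,5,5,4,5,5,5,5,5,5,5,5,5
6,2,5,5,5,5,5,5,4,5,5,4,5,5,5,5,5,5,5,5,5
7,4,5,5,5,5,5,5,5,4,5,4,5,5,5,5,5,5,5,5,5
8,4,3,5,5,5,4,5,5,5,5,4,5,5,5,5,5,5,5,5,5
9,4,5,5,5,4,5,5,5,4,4,4,5,5,5,5,5,5,5,5,5
10,4,4,5,4,4,5,4,4,5,3,4,5,5,5,5,5,5,5,5,5
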