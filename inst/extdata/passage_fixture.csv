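size_mm,passed
2.61,1
2.43,1
3.11,1
3.59,0
3.92,1
4.17,0
5.05,1
4.97,0
6.01,1
5.78,0
6.59,0
7.29,0
6.58,0
7.32,0
7.76,0
8.39,0
8.51,0
8.2,0
8.67,0
10.2,0
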