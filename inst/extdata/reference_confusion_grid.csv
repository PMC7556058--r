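eta,gamma,predicted,high,medium,low
0.01,0.97,high,50,4,7
0.01,0.97,medium,4,59,1
0.01,0.97,low,2,1,40
0.03,0.95,high,45,6,1
0.03,0.95,medium,5,58,0
0.03,0.95,low,6,0,47
0.045,0.98,high,55,1,1
0.045,0.98,medium,1,60,1
0.045,0.98,low,0,3,46
0.05,0.96,high,54,6,0
0.05,0.96,medium,1,56,0
0.05,0.96,low,1,2,48
0.055,0.96,high,53,2,5
0.055,0.96,medium,2,58,0
0.055,0.96,low,1,4,43
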