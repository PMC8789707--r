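education,35,40,45,50,55,60,65,70,75,80,85,90,95
5,0.23,0.25,0.28,0.32,0.36,0.41,0.46,0.53,0.61,0.7,0.8,0.92,1.05
8,-0.05,-0.03,0,0.03,0.07,0.12,0.18,0.25,0.33,0.42,0.52,0.63,0.76
11,-0.25,-0.22,-0.2,-0.16,-0.12,-0.07,-0.01,0.05,0.13,0.22,0.33,0.44,0.57
13,-0.35,-0.33,-0.3,-0.27,-0.22,-0.17,-0.12,-0.05,0.03,0.12,0.22,0.34,0.47
16,-0.47,-0.45,-0.43,-0.39,-0.35,-0.3,-0.24,-0.17,-0.09,0,0.1,0.21,0.34
18,-0.54,-0.52,-0.5,-0.46,-0.42,-0.37,-0.31,-0.24,-0.17,-0.08,0.03,0.14,0.27
21,-0.64,-0.62,-0.59,-0.56,-0.52,-0.47,-0.41,-0.34,-0.26,-0.17,-0.07,0.05,0.18
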