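education,35,40,45,50,55,60,65,70,75,80,85,90,95
5,0.2,0.24,0.29,0.33,0.39,0.45,0.51,0.58,0.66,0.74,0.82,0.91,1.01
8,-0.1,-0.06,-0.02,0.03,0.09,0.15,0.21,0.28,0.36,0.44,0.52,0.61,0.71
11,-0.3,-0.26,-0.22,-0.17,-0.12,-0.06,0.01,0.08,0.15,0.23,0.32,0.41,0.5
13,-0.41,-0.37,-0.33,-0.28,-0.22,-0.16,-0.1,-0.03,0.04,0.12,0.21,0.3,0.39
16,-0.54,-0.5,-0.46,-0.41,-0.36,-0.3,-0.23,-0.16,-0.09,-0.01,0.08,0.17,0.26
18,-0.62,-0.58,-0.53,-0.49,-0.43,-0.37,-0.31,-0.24,-0.16,-0.08,0,0.09,0.19
21,-0.72,-0.68,-0.63,-0.58,-0.53,-0.47,-0.41,-0.34,-0.26,-0.18,-0.1,-0.01,0.09
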