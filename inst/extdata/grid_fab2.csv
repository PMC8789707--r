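education,35,40,45,50,55,60,65,70,75,80,85,90,95
5,-0.21,-0.17,-0.12,-0.05,0.03,0.13,0.25,0.39,0.54,0.72,0.93,1.16,1.41
8,-0.4,-0.36,-0.31,-0.24,-0.16,-0.06,0.06,0.2,0.35,0.53,0.74,0.97,1.23
11,-0.49,-0.45,-0.39,-0.33,-0.24,-0.14,-0.03,0.11,0.27,0.45,0.65,0.88,1.14
13,-0.53,-0.48,-0.43,-0.36,-0.28,-0.18,-0.06,0.07,0.23,0.41,0.62,0.85,1.1
16,-0.56,-0.52,-0.47,-0.4,-0.31,-0.22,-0.1,0.04,0.2,0.38,0.58,0.81,1.07
18,-0.58,-0.54,-0.48,-0.42,-0.33,-0.23,-0.12,0.02,0.18,0.36,0.56,0.79,1.05
21,-0.6,-0.56,-0.5,-0.44,-0.35,-0.25,-0.14,,,0.34,0.54,0.77,1.03
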