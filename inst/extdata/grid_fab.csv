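education,35,40,45,50,55,60,65,70,75,80,85,90,95
5,0.28,0.36,0.47,0.61,0.77,0.97,1.21,1.48,1.79,2.15,2.56,3.02,3.54
8,-0.46,-0.37,-0.26,-0.13,0.04,0.23,0.47,0.74,1.06,1.42,1.83,2.29,2.8
11,-0.96,-0.87,-0.76,-0.63,-0.46,-0.26,-0.03,0.24,0.56,0.92,1.33,1.79,2.3
13,-1.22,-1.13,-1.02,-0.89,-0.72,-0.53,-0.29,-0.02,0.3,0.66,1.07,1.53,2.04
16,-1.54,-1.46,-1.35,-1.21,-1.05,-0.85,-0.62,-0.34,-0.03,0.33,0.74,1.2,1.71
18,-1.73,-1.64,-1.53,-1.4,-1.23,-1.03,-0.8,-0.53,-0.21,0.15,0.56,1.02,1.53
21,-1.97,-1.88,-1.78,-1.64,-1.47,-1.28,-1.04,-0.77,-0.45,-0.09,0.32,0.78,1.29
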