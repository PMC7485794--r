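run,pop,w,c1,c2,m,r2
1,40,0.3,1.1,1.1,0.02,0.721
2,40,0.9,1.3,1.3,0.06,0.763
3,40,1.5,1.65,1.65,0.2,0.753
4,40,0.9~0.3,2.8,2.8,0.6,0.773
5,40,0.3~1.5,3.5,3.5,1,0.772
6,50,0.3,1.3,1.65,0.6,0.773
7,50,0.9,1.65,2.8,1,0.758
8,50,1.5,2.8,3.5,0.02,0.759
9,50,0.9~0.3,3.5,1.1,0.06,0.757
10,50,0.3~1.5,1.1,1.3,0.2,0.773
11,60,0.3,1.65,3.5,0.06,0.761
12,60,0.9,2.8,1.1,0.2,0.765
13,60,1.5,3.5,1.3,0.6,0.721
14,60,0.9~0.3,1.1,1.65,1,0.773
15,60,0.3~1.5,1.3,2.8,0.02,0.746
16,70,0.3,2.8,1.3,1,0.739
17,70,0.9,3.5,1.65,0.02,0.779
18,70,1.5,1.1,2.8,0.06,0.687
19,70,0.9~0.3,1.3,3.5,0.2,0.773
20,70,0.3~1.5,1.65,1.1,0.6,0.773
21,80,0.3,3.5,2.8,0.2,0.773
22,80,0.9,1.1,3.5,0.6,0.762
23,80,1.5,1.3,1.1,1,0.733
24,80,0.9~0.3,1.65,1.3,0.02,0.760
25,80,0.3~1.5,2.8,1.65,0.06,0.760
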