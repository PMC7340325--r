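bin_center	weight
-85	0.000597195405022577
-75	0.00114745944116866
-65	0.00203191538654553
-55	0.00331605162874448
-45	0.00498751640804
-35	0.00691344927197552
-25	0.00883186888054476
-15	0.0103981920490138
-5	0.011282632569436
5	0.011282632569436
15	0.0103981920490138
25	0.00883186888054476
35	0.00691344927197552
45	0.00498751640804
55	0.00331605162874448
65	0.00203191538654553
75	0.00114745944116866
85	0.000597195405022577
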