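time,intensity
3,0.4548
3.5,0.3249
4,-0.2612
4.5,0.041
5,0.5644
5.5,0.5898
6,-0.4705
6.5,-0.4854
7,-0.1627
7.5,-0.0901
8,0.3566
8.5,0.4549
9,-0.3819
9.5,0.6105
10,0.1009
10.5,0.6304
11,0.7846
11.5,0.9613
12,1.7629
12.5,3.1611
13,3.7107
13.5,4.2521
14,5.9283
14.5,6.677
15,7.9976
15.5,8.7058
16,10.4728
16.5,11.1603
17,10.4788
17.5,11.5222
18,11.3271
18.5,11.6182
19,12.1851
19.5,11.4776
20,11.9156
20.5,11.9041
21,11.9148
21.5,12.4623
22,12.1618
22.5,11.6961
23,12.1033
23.5,11.4398
24,11.9271
24.5,11.9575
25,12.3161
25.5,11.9216
26,12.1723
26.5,12.2982
27,11.8849
27.5,12.1893
28,11.4844
28.5,11.9812
29,11.7306
29.5,12.5434
30,11.5509
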