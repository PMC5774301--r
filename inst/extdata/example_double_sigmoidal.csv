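time,intensity
3,0.0118
3.5,-0.4907
4,-0.0341
4.5,-0.2185
5,-0.453
5.5,-0.0333
6,-0.2821
6.5,0.6744
7,0.0237
7.5,1.3958
8,1.368
8.5,3.5816
9,5.101
9.5,6.4432
10,8.2672
10.5,8.5977
11,9.4506
11.5,9.471
12,9.9813
12.5,10.3592
13,9.8772
13.5,10.0343
14,9.9923
14.5,10.1575
15,9.7527
15.5,9.6703
16,10.3301
16.5,9.4497
17,10.2585
17.5,9.919
18,9.4885
18.5,9.1563
19,8.9552
19.5,8.117
20,7.3955
20.5,7.0974
21,6.0539
21.5,5.7379
22,5.1437
22.5,4.3586
23,3.9369
23.5,3.5644
24,3.2306
24.5,2.6604
25,2.2345
25.5,2.9929
26,3.0323
26.5,2.5405
27,3.0306
27.5,2.5971
28,2.6844
28.5,2.9179
29,2.7504
29.5,2.7711
30,2.9323
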