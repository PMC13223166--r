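zone,total_removed,patients_with_removal,median_removed,min_removed,max_removed
1,1077,383,1,0,19
2,1131,380,2,0,14
3,1083,372,1,0,17
4,1069,362,1,0,14
5,1044,361,1,0,17
6,1000,350,1,0,13
7,1481,355,2,0,21
8,1641,349,2,0,25
9,922,315,1,0,22
10,946,312,1,0,13
11,2821,410,4,0,46
12,2427,376,3,0,37
13,988,248,0,0,15
14,979,225,0,0,32
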