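run,cs_actual,ga_actual,time_actual,cs_coded,ga_coded,time_coded,activity,predicted_reported
1,3,1.5,16,1,1,0,86,96
2,3,1,24,1,0,1,308,275
3,2.5,1,16,0,0,0,217,239
4,2.5,0.5,24,0,-1,1,480,482
5,2,1,24,-1,0,1,540,546
6,2,1,6,-1,0,-1,477,502
7,3,0.5,16,1,-1,0,214,235
8,2.5,1.5,24,0,1,1,473,488
9,2.5,0.5,6,0,-1,-1,690,672
10,2.5,1,16,0,0,0,222,239
11,2,0.5,16,-1,-1,0,366,352
12,2.5,1.5,6,0,1,-1,462,454
13,2,1.5,16,-1,1,0,329,304
14,2.5,1,16,0,0,0,284,239
15,3,1,6,1,0,-1,483,476
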