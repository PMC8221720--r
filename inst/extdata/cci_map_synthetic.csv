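icd_code,chronic,body_system
042,1,1
070.54,1,1
034.0,0,1
153.9,1,2
174.9,1,2
216.0,0,2
250,1,3
272.4,1,3
244.9,1,3
276.51,0,3
282.60,1,4
285.21,1,4
285.1,0,4
295.90,1,5
296.30,1,5
303.90,1,5
308.0,0,5
332.0,1,6
332.1,1,6
365.11,1,6
369.00,1,6
389.10,1,6
389.18,1,6
382.9,0,6
401.9,1,7
414.01,1,7
428.0,1,7
427.89,0,7
491.21,1,8
493.90,1,8
496,1,8
486,0,8
571.5,1,9
555.9,1,9
540.9,0,9
585.6,1,10
600.00,1,10
599.0,0,10
642.00,1,11
648.00,1,11
650,0,11
696.1,1,12
707.00,1,12
680.9,0,12
714.0,1,13
715.90,1,13
721.90,1,13
724.2,0,13
745.5,1,14
758.0,1,14
765.10,1,15
770.7,1,15
779.3,0,15
907.0,1,16
905.9,1,16
845.00,0,16
797,1,17
799.3,1,17
780.60,0,17
V45.81,1,18
V49.86,1,18
V70.0,0,18
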