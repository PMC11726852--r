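target,test_pos,true_pos,test_neg,true_neg,gold_total
any_reoperation,2347,2212,9204,,
major,570,441,1777,1721,497
infection,103,88,2244,2218,114
nonunion,138,77,2209,2192,94
re_osteosynthesis,233,175,2114,2094,195
secondary_arthroplasty,104,90,2234,,94
minor,1667,1485,680,671,1494
hardware_removal,917,862,1430,1422,870
wound_treatment,753,621,1594,1591,624
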