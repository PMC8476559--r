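table,gene,test,group,category,count
TNFAIP3,TNFAIP3,fisher,control,1,1
TNFAIP3,TNFAIP3,fisher,control,2,337
TNFAIP3,TNFAIP3,fisher,case,1,0
TNFAIP3,TNFAIP3,fisher,case,2,327
TNIP1,TNIP1,fisher,control,1,0
TNIP1,TNIP1,fisher,control,2,338
TNIP1,TNIP1,fisher,case,1,2
TNIP1,TNIP1,fisher,case,2,325
IL12B,IL12B,fisher,control,1,0
IL12B,IL12B,fisher,control,2,338
IL12B,IL12B,fisher,case,1,3
IL12B,IL12B,fisher,case,2,324
TBX21,TBX21,fisher,control,1,0
TBX21,TBX21,fisher,control,2,338
TBX21,TBX21,fisher,case,1,3
TBX21,TBX21,fisher,case,2,324
TLR7_M,TLR7,none,control,1,131
TLR7_M,TLR7,none,control,2,0
TLR7_M,TLR7,none,case,1,34
TLR7_M,TLR7,none,case,2,1
C4A,C4A,chisq,control,1,39
C4A,C4A,chisq,control,2,250
C4A,C4A,chisq,control,3-4,49
C4A,C4A,chisq,case,1,47
C4A,C4A,chisq,case,2,242
C4A,C4A,chisq,case,3-4,38
C4B,C4B,chisq,control,1,43
C4B,C4B,chisq,control,2,223
C4B,C4B,chisq,control,3,41
C4B,C4B,chisq,control,4,31
C4B,C4B,chisq,case,1,62
C4B,C4B,chisq,case,2,193
C4B,C4B,chisq,case,3,51
C4B,C4B,chisq,case,4,21
CCL3L1,CCL3L1,chisq,control,0,17
CCL3L1,CCL3L1,chisq,control,1,98
CCL3L1,CCL3L1,chisq,control,2,125
CCL3L1,CCL3L1,chisq,control,3,56
CCL3L1,CCL3L1,chisq,control,4-6,42
CCL3L1,CCL3L1,chisq,case,0,18
CCL3L1,CCL3L1,chisq,case,1,92
CCL3L1,CCL3L1,chisq,case,2,134
CCL3L1,CCL3L1,chisq,case,3,41
CCL3L1,CCL3L1,chisq,case,4-6,42
CCL3L3,CCL3L3,chisq,control,0,0
CCL3L3,CCL3L3,chisq,control,1,83
CCL3L3,CCL3L3,chisq,control,2,141
CCL3L3,CCL3L3,chisq,control,3,91
CCL3L3,CCL3L3,chisq,control,4-6,23
CCL3L3,CCL3L3,chisq,case,0,17
CCL3L3,CCL3L3,chisq,case,1,74
CCL3L3,CCL3L3,chisq,case,2,118
CCL3L3,CCL3L3,chisq,case,3,84
CCL3L3,CCL3L3,chisq,case,4-6,34
C4B_low,C4B,fisher,control,1,43
C4B_low,C4B,fisher,control,2-4,295
C4B_low,C4B,fisher,case,1,62
C4B_low,C4B,fisher,case,2-4,265
CCL3L3_null,CCL3L3,fisher,control,0,0
CCL3L3_null,CCL3L3,fisher,control,1-6,338
CCL3L3_null,CCL3L3,fisher,case,0,17
CCL3L3_null,CCL3L3,fisher,case,1-6,310
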