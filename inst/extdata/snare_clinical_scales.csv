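patient,sex,vineland_abc,gmfcs,macs,cfcs,eeg_severity
P01,M,46,5,4,5,2
P02,M,44,5,5,5,7
P03,M,27,5,5,5,8
P04,M,35,5,5,5,3
P05,M,38,5,4,5,6
P06,F,58,2,3,4,1
P07,M,60,1,2,1,4
P08,M,56,2,4,3,1
P09,M,53,2,4,4,7
P10,F,77,1,1,1,5
P11,F,96,1,1,2,1
P12,F,60,1,1,2,5
P13,M,101,1,1,2,1
P14,F,46,5,5,4,8
P15,F,22,5,5,5,6
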