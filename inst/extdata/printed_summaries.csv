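table,participant,measure,phase,mean,sd
wmft,group,fas,pre,14,4
wmft,group,fas,post,28,4
wmft,group,fas,change,14,3
wmft,group,time,pre,101,20
wmft,group,time,post,71,8
wmft,group,time,change,30,14
assessment,1,sr,pre,53,12
assessment,1,sr,post,83,13
assessment,1,sr,change,30,17
assessment,1,rt,pre,664,165
assessment,1,rt,post,550,138
assessment,1,rt,change,114,71
assessment,2,sr,pre,46,11
assessment,2,sr,post,87,22
assessment,2,sr,change,42,30
assessment,2,rt,pre,693,143
assessment,2,rt,post,552,142
assessment,2,rt,change,141,185
assessment,3,sr,pre,58,14
assessment,3,sr,post,71,6
assessment,3,sr,change,13,9
assessment,3,rt,pre,828,29
assessment,3,rt,post,796,22
assessment,3,rt,change,32,43
assessment,4,sr,pre,57,8
assessment,4,sr,post,73,16
assessment,4,sr,change,17,13
assessment,4,rt,pre,715,121
assessment,4,rt,post,577,129
assessment,4,rt,change,139,115
assessment,5,sr,pre,65,8
assessment,5,sr,post,81,10
assessment,5,sr,change,16,4
assessment,5,rt,pre,796,33
assessment,5,rt,post,698,100
assessment,5,rt,change,99,103
headline,group,sr,change,23,12
headline,group,rt,change,105,44
headline,group,fas,change,14,3
headline,group,time,change,30,14
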