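# Published group-level gait parameter summary (mean, sample SD) from a
# six-subject study of parkinsonian gait with walker-delivered haptic speed
# cues. Conditions: c = unassisted, w = conventional walker, ml/mm/mh =
# motorized walker with low/medium/high speed cue. Units: s for times,
# cm for lengths/heights, cm/s for velocity.
parameter,condition,mean,sd
gct,c,1.29,0.25
sw,c,0.35,0.05
st,c,0.94,0.22
ids,c,0.24,0.69
tds,c,0.22,0.03
sl,c,92.98,1.24
sh,c,21.19,3.14
vel,c,75.28,12.99
gct,w,1.34,0.21
sw,w,0.39,0.06
st,w,0.95,0.2
ids,w,0.24,0.11
tds,w,0.22,0.12
sl,w,70.61,27.70
sh,w,20.78,3.40
vel,w,65.89,17.36
gct,ml,1.68,0.28
sw,ml,0.43,0.10
st,ml,1.25,0.28
ids,ml,0.28,0.14
tds,ml,0.25,0.13
sl,ml,49.72,12.58
sh,ml,14.52,4.09
vel,ml,29.24,7.94
gct,mm,1.4,0.2
sw,mm,0.38,0.06
st,mm,1.02,0.17
ids,mm,0.22,0.01
tds,mm,0.21,0.13
sl,mm,68.59,11.86
sh,mm,19.02,3.31
vel,mm,52.80,10.56
gct,mh,1.31,0.13
sw,mh,0.38,0.06
st,mh,0.94,0.1
ids,mh,0.21,0.06
tds,mh,0.21,0.05
sl,mh,74.76,12.11
sh,mh,21.08,2.97
vel,mh,67.33,11.67
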