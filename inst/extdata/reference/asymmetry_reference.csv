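# Published bilateral asymmetry indices (percent; positive = left larger)
# for straight walking in the same six-subject walker study. upper_bound =
# TRUE marks values printed only as "< value".
parameter,condition,ia_pct,upper_bound
gct,c,6.7,FALSE
gct,ml,0.56,FALSE
gct,mm,0.1,TRUE
gct,mh,0.1,TRUE
gct,w,0.53,FALSE
sh,c,5.7,FALSE
sh,ml,-3.99,FALSE
sh,mm,3.46,FALSE
sh,mh,2.12,FALSE
sh,w,1.48,FALSE
sl,c,-1.8,FALSE
sl,ml,-2.10,FALSE
sl,mm,1.44,FALSE
sl,mh,1.33,FALSE
sl,w,-3.25,FALSE
vel,c,3.4,FALSE
vel,ml,-9.50,FALSE
vel,mm,1.48,FALSE
vel,mh,2.03,FALSE
vel,w,-2.75,FALSE
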