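# Published support-phase ratios (percent of gait cycle / stance) for the
# same six-subject walker study; condition codes as in
# group_parameter_summary.csv.
ratio,condition,value_pct
st_gct,c,72.76
st_gct,ml,74.40
st_gct,mm,73.10
st_gct,mh,71.53
st_gct,w,70.98
ids_gct,c,18.75
ids_gct,ml,16.78
ids_gct,mm,15.66
ids_gct,mh,15.72
ids_gct,w,17.48
tds_gct,c,16.88
tds_gct,ml,14.94
tds_gct,mm,15.09
tds_gct,mh,16.18
tds_gct,w,16.59
ids_st,c,25.77
ids_st,ml,22.56
ids_st,mm,21.43
ids_st,mh,21.98
ids_st,w,24.63
tds_st,c,22.45
tds_st,ml,20.08
tds_st,mm,20.65
tds_st,mh,22.62
tds_st,w,23.37
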