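name,mode,depth_min_m,depth_max_m
bottom_trawl,benthic,NA,NA
set_longline,benthic,NA,NA
pot,benthic,NA,NA
dredge,benthic,NA,NA
midwater_trawl,pelagic,30,350
drifting_longlines,pelagic,0,400
squid_jigger,pelagic,0,150
purse_seines,unspecified,NA,NA
trawlers,unspecified,NA,NA
fishing,unspecified,NA,NA
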