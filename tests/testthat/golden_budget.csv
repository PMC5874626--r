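station,time_point,production,nh4_efflux,nox_efflux,din_efflux,din_sem,accumulation,denit_raw,denit,negligible,nh4_oxidation,denit_fraction,incomplete
S,10,10,2,1,3,0.57735,1,6,6,FALSE,7,0.6,FALSE
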