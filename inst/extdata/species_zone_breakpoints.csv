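species,clr_lo,clr_hi,mcr_lo,mcr_hi,wtr_lo,wtr_hi
eastern_hemlock,-37.2,-26.1,-26.1,-20.6,-20.6,-9.5
sweet_birch,-37.2,-26.1,-23.3,-20.6,-20.6,-3.9
tulip_poplar,-31.7,-17.8,-17.8,-12.2,-12.2,-3.9
chestnut_oak,-31.7,-20.6,-20.6,-17.8,-17.8,-3.9
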