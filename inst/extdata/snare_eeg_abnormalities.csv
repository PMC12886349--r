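patient,categories,published_rank,rank_reproducible
P01,focal_transient,2,TRUE
P02,slow_pdr;ap_gradient,7,FALSE
P03,slow_pdr;ap_gradient,8,FALSE
P04,epileptiform_discharge,3,TRUE
P05,epileptiform_discharge;focal_transient;ap_gradient,6,FALSE
P06,,1,TRUE
P07,diffuse_beta,4,TRUE
P08,,1,TRUE
P09,slow_pdr;ap_gradient,7,FALSE
P10,slow_pdr,5,TRUE
P11,,1,TRUE
P12,focal_transient;slow_pdr,5,FALSE
P13,,1,TRUE
P14,burst_suppression;epileptiform_discharge,8,TRUE
P15,epileptiform_discharge;focal_transient,6,FALSE
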