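sample_id,assay,n_total,n_mut_pos,n_wt_pos,droplet_volume_nl,reaction_fraction,plasma_ml
P001,EGFR_L858R,15000,42,5210,0.85,0.25,1
P001,TP53_R175H,15000,3,5190,0.85,0.25,1
P002,KRAS_G12D,14200,0,4105,0.85,0.25,1
P003,EGFR_E19del,15800,880,3950,0.85,0.25,1
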