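group,lower_um,upper_um,n_particles,n_tomograms,thickness_nm,thickness_sd_nm,bfactor_A2,bfactor_se_A2,resolution_A
backside_0_1um,0,1,5702,18,213,29,321,21,6.8
backside_1_2um,1,2,8655,26,214,28,284,13,6.2
backside_2_3um,2,3,6941,21,216,27,321,11,6.8
backside_3_4um,3,4,7623,26,205,30,311,13,6.6
backside_4_5um,4,5,7146,25,195,25,299,17,6.8
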