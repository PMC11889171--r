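group,set,lower_nm,upper_nm,n_particles,n_tomograms,thickness_nm,thickness_sd_nm,bfactor_A2,bfactor_se_A2,resolution_A
all,group,NA,NA,10000,163,189,30,218,17,5.8
lt30_matched,group,0,30,10000,163,189,30,276,14,6.7
gt30_matched,group,30,NA,10000,163,189,30,188,10,5.5
depth_00_05,group,0,5,25,29,186,30,NA,NA,NA
depth_00_05,control,0,5,25,29,186,30,NA,NA,NA
depth_05_10,group,5,10,1243,152,188,30,1390,160,15.8
depth_05_10,control,5,10,1243,152,188,30,417,30,9.7
depth_10_15,group,10,15,2967,162,186,29,504,33,9.9
depth_10_15,control,10,15,2967,162,186,29,320,19,7.6
depth_15_20,group,15,20,4143,161,189,30,434,20,8.2
depth_15_20,control,15,20,4143,161,189,30,311,15,7.1
depth_20_25,group,20,25,4795,163,191,30,340,16,7.2
depth_20_25,control,20,25,4795,163,191,30,307,10,6.9
depth_25_30,group,25,30,4946,162,192,31,334,14,7.2
depth_25_30,control,25,30,4946,162,192,31,299,17,6.7
depth_30_35,group,30,35,5119,162,192,31,317,16,7.0
depth_30_35,control,30,35,5119,162,192,31,293,19,6.7
depth_35_40,group,35,40,5048,161,192,31,312,12,7.1
depth_35_40,control,35,40,5048,161,192,31,308,14,6.9
depth_40_45,group,40,45,5163,162,192,32,297,16,6.9
depth_40_45,control,40,45,5163,162,192,32,307,14,6.8
depth_45_50,group,45,50,5076,163,193,32,305,13,6.8
depth_45_50,control,45,50,5076,163,193,32,318,15,7.2
depth_50_55,group,50,55,5170,161,191,31,309,18,6.8
depth_50_55,control,50,55,5170,161,191,31,291,12,6.8
depth_55_60,group,55,60,5235,162,194,30,305,16,6.8
depth_55_60,control,55,60,5235,162,194,30,315,15,6.8
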