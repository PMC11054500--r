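feature,mean,sd
curve_mean,66.34465024661446,12.236415873522327
curve_median,57.8148844442004,16.118846280745593
curve_std,47.24756815894547,3.9338055761421975
curve_iqr,71.14252270838855,13.364642711630657
curve_ac1value,0.04549980221110569,0.05445514556575753
curve_ac1lag,4.46,1.62319052324349
curve_sampen,2.004702515326015,0.22587698137722562
crows_mean,2.4333636593480055,0.9605745111810997
crows_median,2.194794277004068,0.6904078981348131
crows_std,1.460775258034729,0.8673252303144935
crows_iqr,1.6801511999364385,0.7983893372988647
crows_ac1value,0.04896806949750943,0.05564564121236399
crows_ac1lag,3.37,1.4045740574381556
crows_sampen,2.0185362749393136,0.19648332833889368
speed_mean,1.3582249657518877,0.09791662726652496
speed_median,1.3584433647758485,0.0978747764180967
speed_std,0.14098242720405446,0.006929799850124391
speed_iqr,0.18894653657157012,0.0142682500652797
speed_ac1value,0.05585732050109777,0.04773541987473728
speed_ac1lag,3.24,1.215389533101103
speed_sampen,2.224459555396942,0.19875743744791094
quality_mean,5.671761708571641,2.3618191169651035
quality_median,5.387788580047225,2.421604285156588
quality_std,1.1044087375870488,0.1786535933517889
quality_iqr,1.1250730848508608,0.13346434850075953
quality_ac1value,0.05721411682964765,0.05279441003552985
quality_ac1lag,3.18,1.32100359766751
quality_sampen,1.8001051517413087,0.2075991336947259
heading_mean,184.05310681915043,65.05179966104764
heading_median,186.00235371075578,74.6215265649518
heading_std,62.354114319576425,51.10273010840892
heading_iqr,109.40920058181868,95.85187785102039
heading_ac1value,0.5233555611948475,0.23954563762550068
heading_ac1lag,16.54,18.677172368342262
heading_sampen,1.0113491897615554,0.840570887502542
deltaheading_mean,6.7265006594155015,12.547523788617422
deltaheading_median,6.138092843393203,10.368871827932136
deltaheading_std,13.130660593779995,12.708098068361473
deltaheading_iqr,11.772069967245818,5.565510940450275
deltaheading_ac1value,0.05570312792351315,0.054644743694056135
deltaheading_ac1lag,2.95,0.9782999065065411
deltaheading_sampen,1.8509374801925125,0.47826516192635005
fs_mean,1.2402631288531902,0.21601793432779334
fs_median,1,0
fs_std,1.0958367564494391,1.290945005494538
fs_iqr,0.1,0.30151134457776363
fs_ac1value,0.0288831526503975,0.055365696793278484
fs_ac1lag,3.92,2.0284840336437147
fs_sampen,0.22633101186845195,0.21564734836727797
q_above_tr,0.26610179429360725,0.7762834890985723
s_above_tr,0,0
delta_distance,1324.92266486454,749.4492354552909
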