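# First-round descriptive summary of the ten asymmetry parameters in the
# original multicenter validation study (15 back-view photographs of AIS
# patients, 12 trained observers). Angles in degrees; SA/WA/PA/TA are
# hemitrunk area parameters. sd = standard deviation over the 15 per-photo
# values; iqr = interquartile range; sem = printed standard error of
# measurement.
measure,n,min,max,mean,sd,median,iqr,sem
SHA,15,-7.5,2.43,-2.5,2.6,-2.8,3.83,0.30
AHA,15,-7.8,-0.85,-4.4,2.2,-3.9,3,1.17
WHA,15,-3.1,6.58,2.0,3.0,1.7,3.7,0.57
LWA,15,128.4,157.18,144.8,9.5,145.9,17.4,0.95
RWA,15,132.3,163.58,147.9,8.1,146.7,12.1,1.3
WAD,15,-35.2,24.88,-3.1,14.9,-6.4,21.8,1.15
SA,15,0.80,1.14,0.94,0.09,0.93,0.1,0.02
WA,15,0.52,0.93,0.71,0.12,0.69,0.2,0.06
PA,15,0.45,1.69,0.83,0.3,0.78,0.3,0.12
TA,15,0.64,1.06,0.81,0.12,0.81,0.2,0.05
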