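variable,cluster,n,mean,sd
iq,1,67,98.57,18.07
iq,2,55,101.99,17.02
iq,3,42,105.82,18.66
ppt_hands,1,67,32.47,9.30
ppt_hands,2,55,34.18,8.42
ppt_hands,3,42,37.58,7.87
ppt_assemble,1,67,19.91,7.63
ppt_assemble,2,55,21.79,7.82
ppt_assemble,3,42,23.27,8.18
vp,1,67,105.78,14.13
vp,2,55,109.62,11.83
vp,3,42,108.86,16.14
mc,1,67,95.87,17.60
mc,2,55,102.73,15.88
mc,3,42,99.79,18.73
vmi,1,67,98.04,19.01
vmi,2,55,102.38,14.41
vmi,3,42,100.21,16.51
vf_se,1,67,14.01,4.42
vf_se,2,55,16.00,6.00
vf_se,3,42,16.36,5.12
vf_ph,1,67,4.42,2.65
vf_ph,2,55,4.65,3.08
vf_ph,3,42,4.90,2.95
rvp,1,67,0.89,0.09
rvp,2,55,0.91,0.07
rvp,3,42,0.91,0.07
soc,1,67,5.46,3.31
soc,2,55,5.73,2.48
soc,3,42,5.67,2.16
swm,1,67,-52.15,27.57
swm,2,55,-47.58,28.25
swm,3,42,-39.90,24.95
ied,1,67,-46.00,21.98
ied,2,55,-42.29,22.10
ied,3,42,-47.19,26.75
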