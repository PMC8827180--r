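variable,group,n,mean,sd
iq,ASD,65,92.92,17.45
iq,ADHD,47,109.2,16.99
iq,TDC,52,105.49,15.12
aq_total,ASD,65,44.00,13.85
aq_total,ADHD,47,32.64,9.91
aq_total,TDC,52,33.56,11.13
snap_total,ASD,65,35.75,10.84
snap_total,ADHD,47,41.51,9.61
snap_total,TDC,52,25.52,9.93
socialness,ASD,65,18.60,6.59
socialness,ADHD,47,11.79,5.94
socialness,TDC,52,11.81,5.67
mindreading,ASD,65,12.29,6.15
mindreading,ADHD,47,9.89,5.07
mindreading,TDC,52,8.25,5.04
patterns,ASD,65,6.12,2.85
patterns,ADHD,47,6.34,2.53
patterns,TDC,52,6.08,2.57
details,ASD,65,6.31,2.33
details,ADHD,47,5.79,2.30
details,TDC,52,5.44,2.59
perseveration,ASD,65,10.11,3.79
perseveration,ADHD,47,8.66,2.25
perseveration,TDC,52,8.10,3.01
inattention,ASD,65,14.57,4.40
inattention,ADHD,47,18.38,3.25
inattention,TDC,52,12.77,4.46
hyperactivity,ASD,65,10.98,4.17
hyperactivity,ADHD,47,14.17,4.91
hyperactivity,TDC,52,9.13,5.24
odd,ASD,65,8.18,4.13
odd,ADHD,47,11.94,4.83
odd,TDC,52,8.25,4.79
ppt_hands,ASD,65,30.98,9.93
ppt_hands,ADHD,47,36.99,8.01
ppt_hands,TDC,52,36.17,6.65
ppt_assemble,ASD,65,17.60,7.25
ppt_assemble,ADHD,47,22.00,7.61
ppt_assemble,TDC,52,25.61,6.69
vp,ASD,65,103.06,15.99
vp,ADHD,47,108.04,11.02
vp,TDC,52,113.67,11.48
mc,ASD,65,94.75,18.04
mc,ADHD,47,97.15,17.88
mc,TDC,52,106.52,14.06
vmi,ASD,65,96.06,19.78
vmi,ADHD,47,99.57,16.17
vmi,TDC,52,105.48,11.86
vf_se,ASD,65,14.14,5.06
vf_se,ADHD,47,15.13,4.74
vf_se,TDC,52,16.85,5.61
vf_ph,ASD,65,4.75,2.92
vf_ph,ADHD,47,4.00,2.54
vf_ph,TDC,52,5.02,3.04
rvp,ASD,65,0.89,0.09
rvp,ADHD,47,0.90,0.08
rvp,TDC,52,0.91,0.07
soc,ASD,65,5.65,3.17
soc,ADHD,47,4.81,2.35
soc,TDC,52,6.27,2.42
swm,ASD,65,-54.58,25.12
swm,ADHD,47,-51.77,26.13
swm,TDC,52,-34.73,27.39
ied,ASD,65,-47.23,23.09
ied,ADHD,47,-48.09,20.16
ied,TDC,52,-39.62,25.50
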