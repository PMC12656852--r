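name,mean,sd,min,max,cv,median,n
bw,610.90,66.52,456.00,739.00,10.89,622.50,102
ndf,346.18,64.37,225.00,519.00,18.60,342.00,117
ee,33.24,8.96,7.60,58.00,26.94,34.00,99
dmi,21.17,3.81,9.96,28.90,18.01,21.90,125
omi,20.37,2.69,15.60,25.90,13.22,20.70,55
gei,361.34,88.50,149.00,500.00,24.49,367.26,70
mei,246.38,32.50,189.12,299.00,13.19,241.42,28
ndfi,7.10,1.71,2.58,10.90,24.12,7.21,118
adfi,4.09,1.33,0.79,7.26,32.38,4.55,97
omd,71.39,1.99,66.30,76.10,2.79,71.50,63
ndfd,51.47,10.20,27.80,68.20,19.81,49.40,71
forage,58.71,15.99,9.00,100.00,27.23,60.00,128
ch4_g,381.34,85.15,129.00,510.00,22.33,392.00,117
ch4_mj,22.52,5.23,8.81,34.17,23.23,22.68,134
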