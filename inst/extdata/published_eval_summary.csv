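rank,model_id,obs_mean,obs_sd,pred_mean,pred_sd,r2,r,ccc,mu,rmspe,rmspe_pct,ect_pct,er_pct,ed_pct,rsr,n
1,38,392.87,91.04,430.31,65.10,0.66,0.81,0.69,-0.49,64.86,16.51,33.32,1.97,66.16,0.71,47
2,12,415.84,58.86,381.94,32.92,0.72,0.85,0.58,0.77,48.51,11.67,48.83,12.38,41.01,0.82,24
3,21,396.71,68.58,386.14,44.15,0.33,0.57,0.51,0.19,57.18,14.41,3.42,0.74,96.75,0.83,107
4,33,398.59,69.92,410.82,51.63,0.34,0.58,0.55,-0.20,58.69,14.72,4.34,3.36,93.46,0.84,83
5,5,24.08,3.84,25.50,2.32,0.40,0.63,0.51,-0.48,3.26,13.54,19.03,0.09,83.88,0.85,28
6,39,23.22,4.48,23.78,4.10,0.35,0.59,0.58,-0.13,3.92,16.86,2.02,13.79,85.08,0.87,111
7,22,23.24,4.56,21.75,2.39,0.32,0.57,0.43,0.45,4.04,17.37,13.57,0.21,86.92,0.88,125
8,32,396.71,68.58,408.27,55.99,0.30,0.55,0.53,-0.19,60.95,15.36,3.59,8.98,88.33,0.89,107
9,35,396.71,68.58,381.47,57.03,0.30,0.55,0.53,0.24,62.07,15.65,6.03,9.68,85.17,0.90,107
10,3,371.13,82.79,397.45,87.17,0.38,0.62,0.59,-0.31,78.11,21.05,11.35,21.08,69.18,0.94,56
11,30,396.71,68.58,370.26,53.63,0.30,0.55,0.49,0.44,64.82,16.34,16.66,6.03,78.10,0.95,107
12,25,376.39,76.41,327.89,53.50,0.47,0.69,0.51,0.76,73.30,19.47,43.78,0.02,57.54,0.96,43
13,4,23.24,4.56,25.40,3.52,0.30,0.55,0.47,-0.54,4.49,19.31,23.31,5.13,72.19,0.98,125
14,18,396.71,68.58,400.21,73.90,0.30,0.55,0.55,-0.05,67.52,17.02,0.27,28.71,71.96,0.98,107
15,20,396.71,68.58,415.31,68.95,0.30,0.55,0.53,-0.27,67.54,17.03,7.58,21.38,71.92,0.98,107
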