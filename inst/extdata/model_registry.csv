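id,label,alt_label,animal,output_unit,form,predictors,omd_scale,expression,equation
1,Kriss,,Dairy,MJ_d,linear,dmi,1,"(75.42 + 94.28*dmi) * 0.05524","CH4 (MJ/d) = (75.42 + 94.28 x DMI) x 0.05524 (MJ/g of CH4)"
2,Axelsson,,Dairy,MJ_d,quadratic,dmi,1,"-2.07 + 2.636*dmi - 0.105*dmi^2","CH4 (MJ/d) = -2.07 + 2.636 x DMI - 0.105 x DMI^2"
3,Yan et al. (2000),,Dairy,g_d,linear,gei,1,"(3.23 + 0.055*gei)/0.05565","CH4 (g/d) = (3.23 + 0.055 x GEI)/0.05565"
4,Mills et al. (2003),,Dairy,MJ_d,linear,dmi,1,"5.93 + 0.92*dmi","CH4 (MJ/d) = 5.93 + 0.92 x DMI"
5,Mills et al. (2003),,Dairy,MJ_d,linear,mei,1,"8.25 + 0.07*mei","CH4 (MJ/d) = 8.25 + 0.07 x MEI"
6,Mills et al. (2003),,Dairy,g_d,exponential,dmi,1,"56.27*(1 - exp(-0.028*dmi))/0.05565","CH4 (g/d) = 56.27 x (1 - exp(-0.028 x DMI))/0.05565"
7,IPCC Tier 2,,All,g_d,linear,gei,1,"0.065*gei/0.05565","CH4 (g/d) = 0.065 x GEI/0.05565"
8,Ellis et al. (2007),,Dairy,g_d,linear,ndfi,1,"(3.14 + 2.11*ndfi)/0.05565","CH4 (g/d) = (3.14 + 2.11 x NDFI)/0.05565"
9,Ellis et al. (2007),,Dairy,g_d,linear,dmi;adfi;ndfi,1,"(2.16 + 0.493*dmi - 1.36*adfi + 1.97*ndfi)/0.05565","CH4 (g/d) = (2.16 + 0.493 x DMI - 1.36 x ADFI + 1.97 x NDFI)/0.05565"
10,Ellis et al. (2007),,Dairy,g_d,linear,dmi,1,"(3.23 + 0.809*dmi)/0.05565","CH4 (g/d) = (3.23 + 0.809 x DMI)/0.05565"
11,Ellis et al. (2007),,Dairy,g_d,linear,mei,1,"(4.08 + 0.068*mei)/0.05565","CH4 (g/d) = (4.08 + 0.068 x MEI)/0.05565"
12,Ellis et al. (2007),,Dairy,g_d,linear,mei;forage,1,"(1.21 + 0.059*mei + 0.093*forage)/0.05565","CH4 (g/d) = (1.21 + 0.059 x MEI + 0.093 x Forage)/0.05565"
13,Ellis et al. (2007),,Dairy,g_d,linear,forage,1,"(8.56 + 0.139*forage)/0.05565","CH4 (g/d) = (8.56 + 0.139 x Forage)/0.05565"
14,Ellis et al. (2007),,Dairy,g_d,linear,adfi,1,"(5.87 + 2.43*adfi)/0.05565","CH4 (g/d) = (5.87 + 2.43 x ADFI)/0.05565"
15,Ellis et al. (2007),,All,MJ_d,linear,dmi;adfi;ndfi,1,"3.41 + 0.520*dmi - 0.996*adfi + 1.15*ndfi","CH4 (MJ/d) = 3.41 + 0.520 x DMI - 0.996 x ADFI + 1.15 x NDFI"
16,Ellis et al. (2007),,All,MJ_d,linear,dmi,1,"3.272 + 0.736*dmi","CH4 (MJ/d) = 3.272 + 0.736 x DMI"
17,Moate et al.,,Dairy,g_d,product,ee;dmi,1,"(24.51 - 0.0788*ee)*dmi","CH4 (g/d) = (24.51 - 0.0788 x EE) x DMI"
18,Hristov et al.,Moate et al. (2011),Dairy,g_d,linear,dmi,1,"2.54 + 19.14*dmi","CH4 (g/d) = 2.54 + 19.14 x DMI"
19,Nielsen et al.,,Dairy,g_d,linear,dmi,1,"(1.26*dmi)/0.05565","CH4 (g/d) = (1.26 x DMI)/0.05565"
20,Ramin and Huhtanen (2013),,Dairy,g_d,linear,dmi,1,"(62 + 25*dmi)*16.0/22.4","CH4 (g/d) = (62 + 25 x DMI) x 16.0/22.4"
21,Ramin and Huhtanen (2013),,All,g_d,quadratic,dmi,1,"(20 + 35.8*dmi - 0.5*dmi^2)*16.0/22.4","CH4 (g/d) = (20 + 35.8 x DMI - 0.5 x DMI^2) x 16.0/22.4"
22,Ramin and Huhtanen (2013),,All,MJ_d,quadratic,dmi,1,"0.797 + 1.427*dmi - 0.020*dmi^2","CH4 (MJ/d) = 0.797 + 1.427 x DMI - 0.020 x DMI^2"
23,Storlien et al.,,Dairy,g_d,linear,dmi,1,"(-1.47 + 1.28*dmi)/0.05565","CH4 (g/d) = (-1.47 + 1.28 x DMI)/0.05565"
24,Storlien et al.,,Dairy,g_d,linear,ndfi,1,"(-2.76 + 3.74*ndfi)/0.05565","CH4 (g/d) = (-2.76 + 3.74 x NDFI)/0.05565"
25,Moraes et al.,,Dairy,g_d,linear,gei;ndf;ee,1,"(0.225 + 0.042*gei + 0.0125*ndf - 0.0329*ee)/0.05565","CH4 (g/d) = (0.225 + 0.042 x GEI + 0.0125 x NDF - 0.0329 x EE)/0.05565"
26,Moraes et al.,,Dairy,g_d,linear,gei,1,"(3.247 + 0.043*gei)/0.05565","CH4 (g/d) = (3.247 + 0.043 x GEI)/0.05565"
27,Charmley et al.,,Dairy,g_d,linear,dmi,1,"38 + 19.22*dmi","CH4 (g/d) = 38 + 19.22 x DMI"
28,Charmley et al.,,Dairy,g_d,linear,gei,1,"(2.14 + 0.058*gei)/0.05565","CH4 (g/d) = (2.14 + 0.058 x GEI)/0.05565"
29,Charmley et al.,,All,g_d,linear,dmi,1,"20.7*dmi","CH4 (g/d) = 20.7 x DMI"
30,Santiago-Juarez et al.,,Dairy,g_d,linear,dmi,1,"(4.544 + 0.773*dmi)/0.05565","CH4 (g/d) = (4.544 + 0.773 x DMI)/0.05565"
31,Patra,,All,MJ_d,exponential,dmi,1,"35.21 - (35.21 + 0.25)*exp(-0.0354*dmi)","CH4 (MJ/d) = 35.21 - (35.21 + 0.25) x exp(-0.0354 x DMI)"
32,Niu et al. (2018),,Dairy,g_d,linear,dmi,1,"107 + 14.5*dmi","CH4 (g/d) = 107 + 14.5 x DMI"
33,Niu et al. (2018),,Dairy,g_d,linear,dmi;ee,1,"160 + 14.2*dmi - 13.5*ee/10","CH4 (g/d) = 160 + 14.2 x DMI - 13.5 x EE/10"
34,Niu et al. (2018),,Dairy,g_d,linear,dmi;ndf,1,"26.0 + 15.3*dmi + 3.42*ndf/10","CH4 (g/d) = 26.0 + 15.3 x DMI + 3.42 x NDF/10"
35,Ribeiro et al.,,Dairy,g_d,linear,dmi,1,"(4.15 + 0.822*dmi)/0.05565","CH4 (g/d) = (4.15 + 0.822 x DMI)/0.05565"
36,Ribeiro et al.,,Dairy,g_d,linear,gei,1,"(3.35 + 0.047*gei)/0.05566","CH4 (g/d) = (3.35 + 0.047 x GEI)/0.05566"
37,Donadia et al. (2023),,Dairy,g_d,linear,ee;omd,10,"550.21 - 0.669*ee - 0.094*omd","CH4 (g/d) = 550.21 - 0.669 x EE - 0.094 x OMD"
38,Donadia et al. (2023),,Dairy,g_d,product,ee;dmi;omd,10,"133.49 - 0.025*ee*dmi + 0.021*omd*dmi","CH4 (g/d) = 133.49 - 0.025 x EE x DMI + 0.021 x OMD x DMI"
39,Wang et al. (2024),,All,MJ_d,linear,dmi;ndfi;adfi,1,"-0.3496 + 0.5941*dmi + 1.388*ndfi - 0.027*adfi","CH4 (MJ/d) = -0.3496 + 0.5941 x DMI + 1.388 x NDFI + (-0.027) x ADFI"
40,Wang et al. (2024),,Dairy,MJ_d,linear,dmi;ndfi,1,"0.3989 + 0.8685*dmi + 0.6675*ndfi","CH4 (MJ/d) = 0.3989 + 0.8685 x DMI + 0.6675 x NDFI"
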