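step_id,step_name,sum_time_min,mean_time_min,sd_time_min,rho_time_tot,rho_time_ct,sum_visits,mean_visits,sd_visits,rho_visits_tot,rho_visits_ct
1,Initial Exposure,235.11,9.04,11.4,0.60,0.09,31,1.19,0.49,-0.12,-0.03
2,IMA dissection,249.12,8.90,5.4,0.12,-0.07,92,3.29,1.88,0.17,0.37
3,Ligation & division of IMA,39.16,1.40,0.9,-0.18,0.40,32,1.14,0.45,0.34,0.32
4,IMV dissection,16.96,3.39,2.7,0.42,0.60,8,1.60,0.89,0.22,0.34
5,Ligation & division of IMV,5.55,0.92,0.5,-0.14,0.60,6,1.00,0.00,NA,NA
6,Splenic flexure mobilization (medial-to-lateral),142.15,12.92,9.5,0.49,0.58,44,4.00,3.38,0.67,0.75
7,Splenic flexure mobilization (lateral-to-medial),105.81,10.05,7.7,0.59,0.63,34,2.27,1.98,0.50,0.49
8,Splenic flexure mobilization (supracolic),124.79,12.83,13.6,0.57,0.57,19,2.71,1.60,0.65,0.65
9,Rectal mobilization (medial-to-lateral),232.28,8.01,7.4,0.13,0.33,92,3.17,2.41,-0.07,0.123
10,Descending & sigmoid colon mobilization (medial-to-lateral),255.16,9.45,8.4,0.31,0.41,86,3.19,2.34,-0.07,0.15
11,Descending & sigmoid colon mobilization (lateral-to-medial),305.56,10.19,8.2,0.11,0.33,90,3.00,1.74,0.14,0.25
12,Posterior rectal dissection,400.68,13.36,13.1,0.57,0.35,261,8.70,5.00,0.42,0.22
13,Anterior rectal dissection,164.71,7.16,6.0,0.29,0.10,118,5.13,3.31,0.43,0.23
14,Right lateral rectal dissection,123.34,4.36,5.1,0.41,0.38,220,7.59,5.18,0.30,0.19
15,Left lateral rectal dissection,177.95,5.93,4.3,0.59,0.64,135,4.50,3.13,0.66,0.56
16,Division of the mesorectum,454.68,15.68,10.7,0.55,0.71,78,2.69,1.75,0.34,0.41
17,Rectal transection,210.04,7.50,5.8,0.40,0.49,39,1.39,0.57,0.13,-0.07
18,Division of the mesocolon,222.05,8.54,4.3,0.37,0.47,37,1.42,0.50,0.04,0.14
19,Proximal colon transection,58.18,2.53,2.0,0.36,0.37,25,1.09,0.29,0.32,0.38
20,Testing for leak (optional),53.05,2.79,2.1,0.07,0.04,26,1.37,0.96,0.42,0.50
21,Colorectal anastomosis,396.52,18.02,8.5,0.16,0.19,45,2.05,1.68,-0.11,-0.13
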