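fa,otter_tail_mean,otter_tail_sd,otter_footpad_mean,otter_footpad_sd,crayfish_mean,crayfish_sd,frog_mean,frog_sd,mollusc_mean,mollusc_sd,fish_clup_mean,fish_clup_sd,fish_cypr_mean,fish_cypr_sd,fish_perc_mean,fish_perc_sd,fish_silur_mean,fish_silur_sd
10:0,0.0,0.03,0.0,0.02,0.5,0.42,0.2,0.19,0.4,1.47,0.1,0.04,0.1,0.08,0.1,0.06,0.0,0.05
12:0,0.2,0.10,0.1,0.07,0.1,0.10,0.6,0.51,0.0,0.01,0.1,0.02,0.2,0.21,0.3,0.26,0.5,0.57
13:0,1.3,2.09,2.3,3.41,0.0,0.00,3.1,3.51,1.7,3.61,0.3,0.30,1.3,1.73,1.0,1.78,1.1,2.25
14:0,3.8,1.05,2.7,0.99,1.5,0.64,1.6,0.47,1.3,0.85,4.1,0.81,2.5,0.96,2.7,0.64,2.5,1.06
14:1,0.7,0.45,1.9,1.04,0.1,0.14,0.2,0.15,1.6,1.95,0.2,0.03,0.4,0.25,0.4,0.25,0.3,0.18
15:0,0.6,0.25,0.4,0.24,0.4,0.19,0.5,0.55,1.3,1.13,0.8,0.24,0.6,0.15,0.6,0.23,0.6,0.11
16:0,14.7,3.33,11.3,5.91,23.3,8.09,17.7,1.6,15.6,4.08,17.0,3.33,15.9,1.98,17.7,2.57,18.9,1.73
16:1,13.7,4.65,26.1,9.01,5.7,2.94,7.1,3.38,13,4.05,15.2,7.16,10.2,3.29,12.4,3.23,8.9,2.77
17:0,1.3,0.47,0.4,0.35,1.7,0.89,0.5,0.63,1.9,0.44,1.9,0.39,1.7,0.46,1.9,0.62,1.8,0.51
17:1,1.6,0.40,1.4,0.51,1.0,0.92,0.5,0.65,1.0,0.83,2.0,0.47,1.2,0.87,1.5,0.73,0.9,0.29
18:0,3.2,1.60,1.4,0.69,10.7,5.57,7.7,2.24,5.2,1.20,3.0,1.32,6.9,2.59,4.8,1.35,7.7,1.76
18:1,29,4.80,31.9,8.71,23.3,5.33,26.7,3.38,9.8,1.37,22.6,5.28,19.8,5.93,18.2,2.96,20.1,2.64
18:2,7.9,3.30,8.7,3.70,9.7,4.12,14.6,3.25,4.3,0.99,3.3,0.33,5.2,2.63,5.4,1.79,3.2,1.74
18:3n6,0.3,0.10,0.1,0.12,0.2,0.26,0.1,0.17,0.3,0.26,0.4,0.06,0.4,0.13,0.4,0.11,0.2,0.07
18:3n3,2.8,0.89,2.4,1.25,1.4,1.37,5.4,4.83,2.5,0.72,3.9,0.62,2.4,1.29,3.4,1.47,1.8,0.76
20:0,0.1,0.07,0.0,0.03,0.3,0.10,0.1,0.13,0.3,0.20,0.2,0.06,0.2,0.11,0.2,0.09,0.3,0.04
20:1,1.6,0.73,0.4,0.37,1.9,1.54,0.2,0.26,8.8,2.98,0.8,0.20,1.5,0.70,1.0,0.91,1.3,0.77
20:2,0.8,0.24,0.3,0.27,0.9,0.42,0.2,0.19,1.2,1.27,0.7,0.21,0.7,0.41,0.5,0.44,0.5,0.28
20:3n6,0.4,0.10,0.2,0.20,0.1,0.12,0.3,0.26,0.1,0.10,0.3,0.07,0.6,0.42,0.3,0.17,0.4,0.11
20:4n6,2.0,0.8,2.3,1.22,2.9,1.31,5.8,2.33,5.8,1.66,2.5,0.92,4.7,2.10,3.6,1.22,5.0,1.90
20:3n3,0.3,0.09,0.1,0.13,0.1,0.16,0.1,0.14,0.0,0.05,0.1,0.03,0.2,0.11,0.3,0.19,0.2,0.07
20:5n3,1.4,0.63,0.5,0.37,8.4,3.83,2.8,0.83,5.8,2.00,4.6,0.86,7.8,4.49,4.3,2.72,6.1,1.36
22:0,0.0,0.02,0.0,0.02,0.0,0.03,0.0,0.04,0.1,0.54,0.0,0.04,0.0,0.00,0.1,0.06,0.1,0.06
22:1,0.1,0.06,0.0,0.01,0.0,0.02,0.0,0.01,0.2,0.45,0.1,0.05,0.0,0.02,0.1,0.06,0.0,0.05
22:2,0.0,0.01,0.0,0.00,0.0,0.00,0.0,0.00,0.0,0.05,0.0,0.02,0.0,0.00,0.0,0.02,0.0,0.02
22:4,0.7,0.25,0.6,0.51,0.0,0.00,0.1,0.15,1.3,0.69,0.4,0.23,0.4,0.38,0.9,0.65,1.0,0.57
22:5,2.5,0.88,1.1,0.98,0.0,0.13,0.6,0.54,3.7,2.09,1.3,0.25,2.2,1.59,3.3,1.32,3.0,0.57
24:0,0.0,0.01,0.0,0.00,0.0,0.00,0.0,0.00,0.0,0.04,0.0,0.02,0.0,0.00,0.1,0.09,0.1,0.08
22:6n4+24:1,3.0,1.11,1.2,1.06,1.9,0.92,1.8,1.27,1.8,1.56,4.3,0.77,6.2,2.59,6.8,2.72,6.4,2.41
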