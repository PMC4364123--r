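roi_id,pipeline,d_smci,s_smci,d_pmci,s_pmci,d_ad,s_ad,flag_pmci,flag_ad,anova_p
3,CV,-0.10,0.36,-0.18,0.38,-0.17,0.34,,,NS
4,CV,-0.12,0.27,-0.18,0.29,-0.20,0.24,,,NS
5,CV,-0.10,0.41,-0.13,0.35,-0.13,0.34,,,NS
6,CV,-0.08,0.32,-0.12,0.26,-0.14,0.28,,,NS
33,CV,-0.10,0.41,-0.13,0.39,-0.22,0.37,,,NS
18,CV,-0.09,0.47,-0.16,0.48,-0.14,0.45,,,NS
19,CV,-0.07,0.30,-0.14,0.29,-0.19,0.28,,,NS
20,CV,-0.10,0.27,-0.17,0.26,-0.23,0.27,,,NS
31,CV,-0.08,0.43,-0.18,0.37,-0.18,0.38,,,NS
22,CV,-0.09,0.36,-0.18,0.35,-0.18,0.41,,,NS
23,CV,-0.07,0.29,-0.15,0.32,-0.19,0.25,,,NS
29,CV,-0.05,0.47,-0.11,0.44,-0.11,0.45,,,NS
30,CV,-0.08,0.54,-0.21,0.55,-0.22,0.51,,,NS
8,CV,-0.17,0.55,-0.18,0.55,-0.38,0.67,,,NS
9,CV,-0.10,0.50,-0.10,0.51,-0.23,0.59,,,NS
10,CV,-0.14,0.45,-0.15,0.38,-0.24,0.44,,,NS
11,CV,-0.13,0.51,-0.16,0.51,-0.31,0.48,,,NS
12,CV,-0.13,0.29,-0.18,0.23,-0.33,0.25,,,NS
13,CV,-0.11,0.32,-0.20,0.35,-0.27,0.33,,,NS
14,CV,-0.11,0.59,-0.14,0.62,-0.30,0.56,,,NS
15,CV,-0.09,0.57,-0.15,0.59,-0.29,0.66,,,NS
16,CV,-0.08,0.64,-0.13,0.57,-0.21,0.58,,,NS
34,CV,-0.19,0.67,-0.28,0.67,-0.55,0.63,,,NS
35,CV,-0.11,0.57,-0.15,0.59,-0.32,0.56,,,NS
37,CV,-0.14,0.57,-0.17,0.59,-0.35,0.52,,,NS
38,CV,-0.11,0.37,-0.11,0.38,-0.30,0.35,,,NS
45,CV,-0.09,0.18,-0.12,0.18,-0.22,0.18,,,NS
46,CV,-0.11,0.16,-0.13,0.14,-0.21,0.14,,omega,0.041
3,FS,-0.09,0.32,-0.21,0.35,-0.19,0.33,,,NS
4,FS,-0.08,0.65,-0.20,0.68,-0.19,0.57,,,NS
5,FS,-0.06,0.36,-0.13,0.37,-0.13,0.37,,,NS
6,FS,-0.05,0.22,-0.15,0.23,-0.16,0.23,,,NS
33,FS,-0.08,0.38,-0.13,0.35,-0.15,0.38,,,NS
18,FS,-0.06,0.23,-0.21,0.20,-0.17,0.22,pi,omega,0.050
19,FS,-0.05,0.32,-0.18,0.31,-0.16,0.30,,,NS
20,FS,-0.08,0.33,-0.22,0.29,-0.21,0.33,,,NS
31,FS,-0.10,0.41,-0.25,0.40,-0.20,0.37,,,NS
22,FS,-0.06,0.35,-0.23,0.34,-0.21,0.40,,,NS
23,FS,-0.05,0.30,-0.17,0.30,-0.20,0.27,,,NS
29,FS,-0.06,0.48,-0.08,0.50,-0.08,0.53,,,NS
30,FS,-0.10,0.65,-0.23,0.66,-0.21,0.62,,,NS
8,FS,-0.14,0.73,-0.24,0.69,-0.33,0.71,,,NS
9,FS,-0.07,0.99,-0.15,0.83,-0.20,0.90,,,NS
10,FS,-0.12,0.62,-0.19,0.63,-0.23,0.61,,,NS
11,FS,-0.12,0.74,-0.16,0.70,-0.25,0.70,,,NS
12,FS,-0.11,0.61,-0.20,0.49,-0.28,0.58,,,NS
13,FS,-0.08,0.54,-0.23,0.54,-0.26,0.48,,,NS
14,FS,-0.11,0.81,-0.17,0.87,-0.25,0.74,,,NS
15,FS,-0.11,0.41,-0.21,0.41,-0.29,0.39,,,NS
16,FS,-0.09,0.62,-0.18,0.63,-0.24,0.63,,,NS
34,FS,-0.21,1.21,-0.33,1.22,-0.59,1.16,,,NS
35,FS,-0.10,1.25,-0.15,1.22,-0.25,1.23,,,NS
37,FS,-0.15,0.80,-0.24,0.77,-0.41,0.73,,,NS
38,FS,-0.13,0.46,-0.21,0.44,-0.34,0.44,,,NS
45,FS,-0.11,0.24,-0.15,0.26,-0.17,0.25,,,NS
46,FS,-0.11,0.37,-0.17,0.38,-0.20,0.37,,,NS
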