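subgroup_type,subgroup,subscale,n,mean_t,sd_t,n_us,mean_t_us,sd_t_us
total,Total,GMH,4370,44.7,8.0,5215,50.0,10.0
total,Total,GMH-2a,4370,44.9,7.6,NA,NA,NA
total,Total,GPH,4370,45.2,9.2,5228,50.0,10.0
total,Total,GPH-2a,4370,45.2,8.3,NA,NA,NA
gender,Male,GMH,2069,45.5,8.0,2206,50.8,10.0
gender,Male,GMH-2a,2069,45.4,7.5,NA,NA,NA
gender,Male,GPH,2069,46.1,9.2,2212,51.2,9.8
gender,Male,GPH-2a,2069,45.6,8.5,NA,NA,NA
gender,Female,GMH,2301,44.1,8.0,3008,49.4,10.0
gender,Female,GMH-2a,2301,44.4,7.6,NA,NA,NA
gender,Female,GPH,2301,44.5,9.1,3015,49.1,10.1
gender,Female,GPH-2a,2301,44.9,8.2,NA,NA,NA
age,18-34,GMH,891,45.6,8.0,1183,48.5,9.7
age,18-34,GMH-2a,891,45.8,7.6,NA,NA,NA
age,18-34,GPH,891,47.8,8.0,1182,51.6,8.4
age,18-34,GPH-2a,891,48.6,7.5,NA,NA,NA
age,35-44,GMH,753,43.8,8.3,863,48.4,10.4
age,35-44,GMH-2a,753,44.0,7.8,NA,NA,NA
age,35-44,GPH,753,45.2,8.2,865,50.1,9.8
age,35-44,GPH-2a,753,45.7,7.5,NA,NA,NA
age,45-54,GMH,646,43.6,8.1,902,48.2,10.3
age,45-54,GMH-2a,646,43.8,7.6,NA,NA,NA
age,45-54,GPH,646,44.6,9.3,910,48.2,10.9
age,45-54,GPH-2a,646,44.7,8.2,NA,NA,NA
age,55-64,GMH,918,43.6,8.0,873,50.3,10.5
age,55-64,GMH-2a,918,43.8,7.6,NA,NA,NA
age,55-64,GPH,918,43.4,9.7,875,48.8,11.3
age,55-64,GPH-2a,918,43.3,8.7,NA,NA,NA
age,65-74,GMH,893,45.9,7.4,715,53.1,8.8
age,65-74,GMH-2a,893,45.8,7.1,NA,NA,NA
age,65-74,GPH,893,45.1,9.5,713,51.0,9.9
age,65-74,GPH-2a,893,44.1,8.4,NA,NA,NA
age,75+,GMH,269,47.3,7.7,679,53.4,8.4
age,75+,GMH-2a,269,46.8,7.4,NA,NA,NA
age,75+,GPH,269,44.9,9.8,683,49.9,9.2
age,75+,GPH-2a,269,43.7,8.7,NA,NA,NA
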