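variable,category,percent
age,18-39,33
age,40-65,44
age,>65,23
gender,Male,47
gender,Female,53
education,Low,29
education,Middle,41
education,High,30
region,North,10
region,East,21
region,South,21
region,West,48
region,Unknown,0
ethnicity,Native,78
ethnicity,Western immigrant,12
ethnicity,Non-western immigrant,10
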