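variable,category,percent
age,18-39,34
age,40-65,44
age,>65,23
gender,Male,49
gender,Female,51
education,Low,30
education,Middle,40
education,High,30
region,North,10
region,East,21
region,South,22
region,West,47
ethnicity,Native,79
ethnicity,Western immigrant,10
ethnicity,Non-western immigrant,11
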