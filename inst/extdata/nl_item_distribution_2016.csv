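item_id,display_value,label,percent
Global01,1,Poor,7.0
Global01,2,Fair,30.9
Global01,3,Good,41.9
Global01,4,Very good,16.2
Global01,5,Excellent,4.1
Global02,1,Poor,4.3
Global02,2,Fair,24.9
Global02,3,Good,44.9
Global02,4,Very good,21.4
Global02,5,Excellent,4.6
Global03,1,Poor,8.1
Global03,2,Fair,33.6
Global03,3,Good,38.9
Global03,4,Very good,15.8
Global03,5,Excellent,3.7
Global04,1,Poor,4.4
Global04,2,Fair,20.4
Global04,3,Good,42.2
Global04,4,Very good,24.8
Global04,5,Excellent,8.3
Global05,1,Poor,5.8
Global05,2,Fair,23.1
Global05,3,Good,45.0
Global05,4,Very good,20.9
Global05,5,Excellent,5.2
Global06,1,Not at all,2.8
Global06,2,A little,9.7
Global06,3,Moderately,18.5
Global06,4,Mostly,17.6
Global06,5,Completely,51.4
Global07,10,Worst pain imaginable,0.4
Global07,9,9,0.9
Global07,8,8,4.5
Global07,7,7,10.4
Global07,6,6,9.8
Global07,5,5,8.8
Global07,4,4,6.3
Global07,3,3,9.2
Global07,2,2,11.5
Global07,1,1,13.6
Global07,0,No pain,24.6
Global08,1,Very severe,2.7
Global08,2,Severe,15.6
Global08,3,Moderate,35.5
Global08,4,Mild,32.3
Global08,5,None,13.9
Global09,1,Poor,4.4
Global09,2,Fair,23.3
Global09,3,Good,45.8
Global09,4,Very good,21.3
Global09,5,Excellent,5.2
Global10,1,Always,1.7
Global10,2,Often,12.0
Global10,3,Sometimes,29.9
Global10,4,Rarely,32.8
Global10,5,Never,23.6
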