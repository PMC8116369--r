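item_id,mean,sd
Global01,2.8,0.9
Global02,3.0,0.9
Global03,2.7,0.9
Global04,3.1,1.0
Global05,3.0,0.9
Global06,4.1,1.2
Global07,3.1,2.7
Global08,3.4,1.0
Global09,3.0,0.9
Global10,3.7,1.0
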