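item_id,trait,a,b1,b2,b3,b4
Global01,composite,2.8,-2.23,-0.86,0.48,1.55
Global02,GMH,3.0,-2.50,-1.16,0.21,1.42
Global03,GPH,3.2,-2.06,-0.72,0.50,1.56
Global04,GMH,2.6,-2.57,-1.34,0.00,1.13
Global05,GMH,2.2,-2.52,-1.23,0.28,1.53
Global06,GPH,2.4,-2.82,-1.89,-1.09,-0.52
Global07,GPH,1.9,-4.04,-1.80,-0.78,0.44
Global08,GPH,1.8,-3.13,-1.72,-0.35,1.01
Global09,composite,2.0,-2.74,-1.28,0.32,1.63
Global10,GMH,1.7,-3.53,-2.08,-0.76,0.49
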