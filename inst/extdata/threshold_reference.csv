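population,subscale,poor_fair,fair_good,good_verygood,verygood_excellent
NL,GMH,38,43,49,56
US,GMH,29,40,48,56
NL,GPH,35,44,51,57
US,GPH,35,42,50,58
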