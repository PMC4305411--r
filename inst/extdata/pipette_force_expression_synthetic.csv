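"expression_pct","force_nN_at_30min"
100,209.699730145729
58,121.796919834299
41,86.0991623077109
38,79.7993246563551
14,29.3552477958679
2,4.03238787138971
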