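"time_min","force_nN"
5,183.77316567651
10,201.25732438196
30,209.699730145729
60,209.997499627543
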