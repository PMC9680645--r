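month,mania,depression
2017-01,none,none
2017-02,mild,none
2017-03,mild,none
2017-04,mild,none
2017-05,none,none
2017-06,moderate,none
2017-07,moderate,none
2017-08,none,none
2017-09,moderate,none
2017-10,none,none
2017-11,moderate,none
2017-12,moderate,none
2018-01,none,none
2018-02,mild,none
2018-03,mild,none
2018-04,none,none
2018-05,moderate,none
2018-06,moderate,none
2018-07,none,none
2018-08,moderate,none
2018-09,moderate,none
2018-10,none,none
2018-11,none,none
2018-12,none,none
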