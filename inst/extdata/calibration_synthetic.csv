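"raw","newton"
0,0
93,0.4428
186,1.0903
279,1.8469
372,2.6845
465,3.588
558,4.5476
651,5.5567
744,6.6101
837,7.7038
930,8.8347
1023,10
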