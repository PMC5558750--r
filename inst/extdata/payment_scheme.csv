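class_index,lower_kcells,upper_kcells,bonus_currency,bonus_milk_equiv
1,1,200,0.04,0.03
2,201,400,0.02,0.015
3,401,500,0,0
4,501,800,-0.01,-0.007
5,801,NA,-0.02,-0.015
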