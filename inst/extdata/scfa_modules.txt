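SCFA001	acetate production (pta-ackA)
K00625,K13788
K00925
//
SCFA002	butyrate production (acetyl-CoA pathway)
K00626
K00074
K01692,K01715
K00248
K01034,K01035,K00929
//
SCFA003	propionate production (succinate pathway)
K01847,K01848
K05606
K01026
//
SCFA004	propionate production (propanediol pathway)
K01699
K13922
K04072
//
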