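embryo_id,day,status,genotype,litter
w01,1,expanded_blastocyst,untyped,litter1
w01,2,hatched,untyped,litter1
w01,3,outgrowth,untyped,litter1
w01,4,outgrowth,untyped,litter1
w01,5,outgrowth,untyped,litter1
w02,1,expanded_blastocyst,untyped,litter2
w02,2,hatched,untyped,litter2
w02,3,outgrowth,untyped,litter2
w02,4,outgrowth,untyped,litter2
w02,5,outgrowth,untyped,litter2
w03,1,expanded_blastocyst,untyped,litter3
w03,2,hatched,untyped,litter3
w03,3,outgrowth,untyped,litter3
w03,4,outgrowth,untyped,litter3
w03,5,outgrowth,untyped,litter3
w04,1,expanded_blastocyst,untyped,litter4
w04,2,hatched,untyped,litter4
w04,3,outgrowth,untyped,litter4
w04,4,outgrowth,untyped,litter4
w04,5,outgrowth,untyped,litter4
w05,1,expanded_blastocyst,untyped,litter1
w05,2,hatched,untyped,litter1
w05,3,outgrowth,untyped,litter1
w05,4,outgrowth,untyped,litter1
w05,5,outgrowth,untyped,litter1
w06,1,expanded_blastocyst,untyped,litter2
w06,2,hatched,untyped,litter2
w06,3,outgrowth,untyped,litter2
w06,4,outgrowth,untyped,litter2
w06,5,outgrowth,untyped,litter2
w07,1,expanded_blastocyst,untyped,litter3
w07,2,hatched,untyped,litter3
w07,3,outgrowth,untyped,litter3
w07,4,outgrowth,untyped,litter3
w07,5,outgrowth,untyped,litter3
w08,1,expanded_blastocyst,untyped,litter4
w08,2,hatched,untyped,litter4
w08,3,outgrowth,untyped,litter4
w08,4,outgrowth,untyped,litter4
w08,5,outgrowth,untyped,litter4
w09,1,expanded_blastocyst,untyped,litter1
w09,2,hatched,untyped,litter1
w09,3,outgrowth,untyped,litter1
w09,4,outgrowth,untyped,litter1
w09,5,outgrowth,untyped,litter1
w10,1,expanded_blastocyst,untyped,litter2
w10,2,hatched,untyped,litter2
w10,3,outgrowth,untyped,litter2
w10,4,outgrowth,untyped,litter2
w10,5,outgrowth,untyped,litter2
w11,1,expanded_blastocyst,untyped,litter3
w11,2,hatched,untyped,litter3
w11,3,outgrowth,untyped,litter3
w11,4,outgrowth,untyped,litter3
w11,5,outgrowth,untyped,litter3
w12,1,expanded_blastocyst,untyped,litter4
w12,2,hatched,untyped,litter4
w12,3,outgrowth,untyped,litter4
w12,4,outgrowth,untyped,litter4
w12,5,outgrowth,untyped,litter4
w13,1,expanded_blastocyst,untyped,litter1
w13,2,hatched,untyped,litter1
w13,3,outgrowth,untyped,litter1
w13,4,outgrowth,untyped,litter1
w13,5,outgrowth,untyped,litter1
w14,1,expanded_blastocyst,untyped,litter2
w14,2,hatched,untyped,litter2
w14,3,outgrowth,untyped,litter2
w14,4,outgrowth,untyped,litter2
w14,5,outgrowth,untyped,litter2
w15,1,expanded_blastocyst,untyped,litter3
w15,2,hatched,untyped,litter3
w15,3,outgrowth,untyped,litter3
w15,4,outgrowth,untyped,litter3
w15,5,outgrowth,untyped,litter3
w16,1,expanded_blastocyst,untyped,litter4
w16,2,hatched,untyped,litter4
w16,3,outgrowth,untyped,litter4
w16,4,outgrowth,untyped,litter4
w16,5,outgrowth,untyped,litter4
w17,1,expanded_blastocyst,untyped,litter1
w17,2,hatched,untyped,litter1
w17,3,outgrowth,untyped,litter1
w17,4,outgrowth,untyped,litter1
w17,5,outgrowth,untyped,litter1
w18,1,expanded_blastocyst,untyped,litter2
w18,2,hatched,untyped,litter2
w18,3,outgrowth,untyped,litter2
w18,4,outgrowth,untyped,litter2
w18,5,outgrowth,untyped,litter2
w19,1,expanded_blastocyst,untyped,litter3
w19,2,hatched,untyped,litter3
w19,3,hatched,untyped,litter3
w19,4,hatched,untyped,litter3
w19,5,hatched,untyped,litter3
w20,1,expanded_blastocyst,untyped,litter4
w20,2,hatched,untyped,litter4
w20,3,hatched,untyped,litter4
w20,4,hatched,untyped,litter4
w20,5,hatched,untyped,litter4
w21,1,expanded_blastocyst,untyped,litter1
w21,2,hatched,untyped,litter1
w21,3,hatched,untyped,litter1
w21,4,hatched,untyped,litter1
w21,5,hatched,untyped,litter1
w22,1,expanded_blastocyst,untyped,litter2
w22,2,hatched,untyped,litter2
w22,3,hatched,untyped,litter2
w22,4,hatched,untyped,litter2
w22,5,hatched,untyped,litter2
w23,1,expanded_blastocyst,untyped,litter3
w23,2,expanded_blastocyst,untyped,litter3
w23,3,expanded_blastocyst,untyped,litter3
w23,4,expanded_blastocyst,untyped,litter3
w23,5,expanded_blastocyst,untyped,litter3
w24,1,expanded_blastocyst,untyped,litter4
w24,2,expanded_blastocyst,untyped,litter4
w24,3,expanded_blastocyst,untyped,litter4
w24,4,expanded_blastocyst,untyped,litter4
w24,5,expanded_blastocyst,untyped,litter4
w25,1,expanded_blastocyst,untyped,litter1
w25,2,expanded_blastocyst,untyped,litter1
w25,3,expanded_blastocyst,untyped,litter1
w25,4,expanded_blastocyst,untyped,litter1
w25,5,expanded_blastocyst,untyped,litter1
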