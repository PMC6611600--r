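embryo_id,day,status,genotype,litter
e01,1,dead,untyped,litter1
e01,2,dead,untyped,litter1
e01,3,dead,untyped,litter1
e01,4,dead,untyped,litter1
e01,5,dead,untyped,litter1
e02,1,compacted_morula,untyped,litter2
e02,2,dead,untyped,litter2
e02,3,dead,untyped,litter2
e02,4,dead,untyped,litter2
e02,5,dead,untyped,litter2
e03,1,compacted_morula,untyped,litter3
e03,2,compacted_morula,untyped,litter3
e03,3,dead,untyped,litter3
e03,4,dead,untyped,litter3
e03,5,dead,untyped,litter3
e04,1,compacted_morula,untyped,litter4
e04,2,compacted_morula,untyped,litter4
e04,3,compacted_morula,untyped,litter4
e04,4,compacted_morula,untyped,litter4
e04,5,compacted_morula,untyped,litter4
e05,1,compacted_morula,-/-,litter5
e05,2,compacted_morula,-/-,litter5
e05,3,blastocyst,-/-,litter5
e05,4,dead,-/-,litter5
e05,5,dead,-/-,litter5
e06,1,compacted_morula,-/-,litter6
e06,2,blastocyst,-/-,litter6
e06,3,dead,-/-,litter6
e06,4,dead,-/-,litter6
e06,5,dead,-/-,litter6
e07,1,compacted_morula,untyped,litter1
e07,2,blastocyst,untyped,litter1
e07,3,dead,untyped,litter1
e07,4,dead,untyped,litter1
e07,5,dead,untyped,litter1
e08,1,compacted_morula,untyped,litter2
e08,2,blastocyst,untyped,litter2
e08,3,dead,untyped,litter2
e08,4,dead,untyped,litter2
e08,5,dead,untyped,litter2
e09,1,compacted_morula,untyped,litter3
e09,2,blastocyst,untyped,litter3
e09,3,dead,untyped,litter3
e09,4,dead,untyped,litter3
e09,5,dead,untyped,litter3
e10,1,blastocyst,+/-,litter4
e10,2,dead,+/-,litter4
e10,3,dead,+/-,litter4
e10,4,dead,+/-,litter4
e10,5,dead,+/-,litter4
e11,1,blastocyst,untyped,litter5
e11,2,dead,untyped,litter5
e11,3,dead,untyped,litter5
e11,4,dead,untyped,litter5
e11,5,dead,untyped,litter5
e12,1,blastocyst,untyped,litter6
e12,2,dead,untyped,litter6
e12,3,dead,untyped,litter6
e12,4,dead,untyped,litter6
e12,5,dead,untyped,litter6
e13,1,blastocyst,untyped,litter1
e13,2,expanded_blastocyst,untyped,litter1
e13,3,expanded_blastocyst,untyped,litter1
e13,4,expanded_blastocyst,untyped,litter1
e13,5,expanded_blastocyst,untyped,litter1
e14,1,blastocyst,untyped,litter2
e14,2,expanded_blastocyst,untyped,litter2
e14,3,expanded_blastocyst,untyped,litter2
e14,4,expanded_blastocyst,untyped,litter2
e14,5,expanded_blastocyst,untyped,litter2
e15,1,expanded_blastocyst,+/+,litter3
e15,2,hatched,+/+,litter3
e15,3,outgrowth,+/+,litter3
e15,4,outgrowth,+/+,litter3
e15,5,outgrowth,+/+,litter3
e16,1,expanded_blastocyst,+/+,litter4
e16,2,hatched,+/+,litter4
e16,3,outgrowth,+/+,litter4
e16,4,outgrowth,+/+,litter4
e16,5,outgrowth,+/+,litter4
e17,1,expanded_blastocyst,+/+,litter5
e17,2,hatched,+/+,litter5
e17,3,outgrowth,+/+,litter5
e17,4,outgrowth,+/+,litter5
e17,5,outgrowth,+/+,litter5
e18,1,expanded_blastocyst,+/+,litter6
e18,2,hatched,+/+,litter6
e18,3,outgrowth,+/+,litter6
e18,4,outgrowth,+/+,litter6
e18,5,outgrowth,+/+,litter6
e19,1,expanded_blastocyst,+/-,litter1
e19,2,hatched,+/-,litter1
e19,3,outgrowth,+/-,litter1
e19,4,outgrowth,+/-,litter1
e19,5,outgrowth,+/-,litter1
e20,1,expanded_blastocyst,+/-,litter2
e20,2,hatched,+/-,litter2
e20,3,outgrowth,+/-,litter2
e20,4,outgrowth,+/-,litter2
e20,5,outgrowth,+/-,litter2
e21,1,expanded_blastocyst,+/-,litter3
e21,2,hatched,+/-,litter3
e21,3,outgrowth,+/-,litter3
e21,4,outgrowth,+/-,litter3
e21,5,outgrowth,+/-,litter3
e22,1,expanded_blastocyst,+/-,litter4
e22,2,hatched,+/-,litter4
e22,3,outgrowth,+/-,litter4
e22,4,outgrowth,+/-,litter4
e22,5,outgrowth,+/-,litter4
e23,1,expanded_blastocyst,+/-,litter5
e23,2,hatched,+/-,litter5
e23,3,outgrowth,+/-,litter5
e23,4,outgrowth,+/-,litter5
e23,5,outgrowth,+/-,litter5
e24,1,expanded_blastocyst,+/-,litter6
e24,2,hatched,+/-,litter6
e24,3,outgrowth,+/-,litter6
e24,4,outgrowth,+/-,litter6
e24,5,outgrowth,+/-,litter6
e25,1,expanded_blastocyst,+/-,litter1
e25,2,hatched,+/-,litter1
e25,3,outgrowth,+/-,litter1
e25,4,outgrowth,+/-,litter1
e25,5,outgrowth,+/-,litter1
e26,1,expanded_blastocyst,+/-,litter2
e26,2,hatched,+/-,litter2
e26,3,outgrowth,+/-,litter2
e26,4,outgrowth,+/-,litter2
e26,5,outgrowth,+/-,litter2
e27,1,expanded_blastocyst,+/-,litter3
e27,2,hatched,+/-,litter3
e27,3,outgrowth,+/-,litter3
e27,4,outgrowth,+/-,litter3
e27,5,outgrowth,+/-,litter3
e28,1,expanded_blastocyst,untyped,litter4
e28,2,hatched,untyped,litter4
e28,3,outgrowth,untyped,litter4
e28,4,outgrowth,untyped,litter4
e28,5,outgrowth,untyped,litter4
e29,1,expanded_blastocyst,untyped,litter5
e29,2,hatched,untyped,litter5
e29,3,outgrowth,untyped,litter5
e29,4,outgrowth,untyped,litter5
e29,5,outgrowth,untyped,litter5
e30,1,expanded_blastocyst,untyped,litter6
e30,2,hatched,untyped,litter6
e30,3,outgrowth,untyped,litter6
e30,4,outgrowth,untyped,litter6
e30,5,outgrowth,untyped,litter6
e31,1,expanded_blastocyst,untyped,litter1
e31,2,hatched,untyped,litter1
e31,3,outgrowth,untyped,litter1
e31,4,outgrowth,untyped,litter1
e31,5,outgrowth,untyped,litter1
e32,1,expanded_blastocyst,untyped,litter2
e32,2,hatched,untyped,litter2
e32,3,outgrowth,untyped,litter2
e32,4,outgrowth,untyped,litter2
e32,5,outgrowth,untyped,litter2
e33,1,expanded_blastocyst,untyped,litter3
e33,2,hatched,untyped,litter3
e33,3,outgrowth,untyped,litter3
e33,4,outgrowth,untyped,litter3
e33,5,outgrowth,untyped,litter3
e34,1,expanded_blastocyst,untyped,litter4
e34,2,hatched,untyped,litter4
e34,3,outgrowth,untyped,litter4
e34,4,outgrowth,untyped,litter4
e34,5,outgrowth,untyped,litter4
e35,1,expanded_blastocyst,untyped,litter5
e35,2,hatched,untyped,litter5
e35,3,outgrowth,untyped,litter5
e35,4,outgrowth,untyped,litter5
e35,5,outgrowth,untyped,litter5
e36,1,expanded_blastocyst,untyped,litter6
e36,2,hatched,untyped,litter6
e36,3,outgrowth,untyped,litter6
e36,4,outgrowth,untyped,litter6
e36,5,outgrowth,untyped,litter6
e37,1,expanded_blastocyst,untyped,litter1
e37,2,expanded_blastocyst,untyped,litter1
e37,3,expanded_blastocyst,untyped,litter1
e37,4,expanded_blastocyst,untyped,litter1
e37,5,hatched,untyped,litter1
e38,1,expanded_blastocyst,untyped,litter2
e38,2,expanded_blastocyst,untyped,litter2
e38,3,expanded_blastocyst,untyped,litter2
e38,4,hatched,untyped,litter2
e38,5,outgrowth,untyped,litter2
e39,1,expanded_blastocyst,untyped,litter3
e39,2,expanded_blastocyst,untyped,litter3
e39,3,expanded_blastocyst,untyped,litter3
e39,4,hatched,untyped,litter3
e39,5,outgrowth,untyped,litter3
e40,1,expanded_blastocyst,untyped,litter4
e40,2,expanded_blastocyst,untyped,litter4
e40,3,hatched,untyped,litter4
e40,4,outgrowth,untyped,litter4
e40,5,outgrowth,untyped,litter4
e41,1,expanded_blastocyst,untyped,litter5
e41,2,expanded_blastocyst,untyped,litter5
e41,3,hatched,untyped,litter5
e41,4,outgrowth,untyped,litter5
e41,5,outgrowth,untyped,litter5
e42,1,expanded_blastocyst,untyped,litter6
e42,2,expanded_blastocyst,untyped,litter6
e42,3,hatched,untyped,litter6
e42,4,outgrowth,untyped,litter6
e42,5,outgrowth,untyped,litter6
e43,1,expanded_blastocyst,untyped,litter1
e43,2,expanded_blastocyst,untyped,litter1
e43,3,outgrowth,untyped,litter1
e43,4,outgrowth,untyped,litter1
e43,5,outgrowth,untyped,litter1
e44,1,expanded_blastocyst,untyped,litter2
e44,2,expanded_blastocyst,untyped,litter2
e44,3,outgrowth,untyped,litter2
e44,4,outgrowth,untyped,litter2
e44,5,outgrowth,untyped,litter2
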