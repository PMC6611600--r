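stage,genotype,resorbed,litter
E3.5,+/+,FALSE,L1
E3.5,+/+,FALSE,L2
E3.5,+/+,FALSE,L3
E3.5,+/-,FALSE,L1
E3.5,+/-,FALSE,L2
E3.5,+/-,FALSE,L3
E3.5,+/-,FALSE,L1
E3.5,+/-,FALSE,L2
E3.5,+/-,FALSE,L3
E3.5,+/-,FALSE,L1
E3.5,+/-,FALSE,L2
E3.5,+/-,FALSE,L3
E3.5,-/-,FALSE,L1
E3.5,-/-,FALSE,L2
E9.5,+/+,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,+/-,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,+/-,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,+/-,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,+/-,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,+/-,FALSE,L4
E9.5,+/-,FALSE,L5
E9.5,untyped,TRUE,L4
E11.5,+/+,FALSE,L6
E11.5,+/-,FALSE,L6
E11.5,+/-,FALSE,L6
E11.5,+/-,FALSE,L6
E11.5,untyped,TRUE,L6
E16.5,+/+,FALSE,L7
E16.5,+/+,FALSE,L7
E16.5,+/-,FALSE,L7
E16.5,+/-,FALSE,L7
E16.5,untyped,TRUE,L7
E17.5,+/+,FALSE,L8
E17.5,+/-,FALSE,L9
E17.5,+/-,FALSE,L8
E17.5,+/-,FALSE,L9
E17.5,+/-,FALSE,L8
E17.5,+/-,FALSE,L9
E17.5,+/-,FALSE,L8
E17.5,+/-,FALSE,L9
E17.5,untyped,TRUE,L8
E17.5,untyped,TRUE,L9
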