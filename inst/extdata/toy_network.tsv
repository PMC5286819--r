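# 9-reaction worked-example network (transcribed fixture, see toy_network())
# columns: id  reversible  met:coeff ...  lb=  ub=
R1 0 A:1 lb=0 ub=1000
R2 0 B:1 lb=0 ub=1000
R3 0 A:1 lb=0 ub=1000
R4 0 A:-1 lb=0 ub=1000
R5 0 A:-1 C:1 lb=0 ub=1000
R6 0 B:-1 C:1 lb=0 ub=1000
R7 0 B:-1 A:1 lb=0 ub=1000
R8 0 B:-1 lb=0 ub=1000
R9 0 C:-1 lb=0 ub=1000
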