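variant	domain	carriers
p.T5N	N-term	1
p.T11A	N-term	2
p.S30F	N-term	3
p.S36T	N-term	1
p.T53I	TM1	3
p.Y80C	TM2	1
p.S85I	TM2	1
p.V95I	TM2	1
p.V103I	TM2	
p.T112M	ECL1	4
p.N123S	TM3	1
p.S127L	TM3	1
p.I137T	TM3	2
p.H158R	ICL2	2
p.S180P	TM4	1
p.F184L	TM4	1
p.F202L	TM5	2
p.M215I	TM5	1
p.A227T	ICL3	1
p.R236C	ICL3	1
p.G238VfsX4	TM6	1
p.N240S	TM6	2
p.I251WfsX34	TM6	1
p.I251L	TM6	
p.G252S	TM6	1
p.V253I	TM6	2
p.C271Y	ECL3	1
p.S295P	TM7	1
p.G323V	C-term	1
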