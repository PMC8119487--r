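FAM1	I.1	0	0	1	2
FAM1	I.2	0	0	2	1
FAM1	II.1	I.1	I.2	1	2
FAM1	II.2	0	0	2	1
FAM1	II.3	I.1	I.2	2	2
FAM1	II.4	0	0	1	1
FAM1	III.1	II.1	II.2	1	2
FAM1	III.2	II.1	II.2	2	2
FAM1	III.3	II.1	II.2	2	1
FAM1	III.4	II.4	II.3	1	2
FAM1	III.5	II.4	II.3	2	1
FAM1	III.6	0	0	2	1
FAM1	IV.1	III.1	III.6	1	2
FAM1	IV.2	III.1	III.6	2	2
FAM1	IV.3	III.1	III.6	1	1
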