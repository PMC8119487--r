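FAM4	I.1	0	0	1	2
FAM4	I.2	0	0	2	1
FAM4	II.1	I.1	I.2	1	2
FAM4	II.2	0	0	2	1
FAM4	II.3	I.1	I.2	2	2
FAM4	II.4	0	0	1	1
FAM4	III.1	II.1	II.2	2	2
FAM4	III.2	II.1	II.2	1	1
FAM4	III.6	II.1	II.2	1	2
FAM4	III.3	II.4	II.3	1	2
FAM4	III.4	II.4	II.3	2	1
FAM4	III.5	0	0	1	1
FAM4	IV.6	III.5	III.1	2	2
FAM4	IV.7	III.5	III.1	1	2
FAM4	IV.8	III.5	III.1	2	1
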