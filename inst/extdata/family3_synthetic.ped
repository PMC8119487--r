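FAM3	I.1	0	0	1	2
FAM3	I.2	0	0	2	1
FAM3	II.1	I.1	I.2	1	2
FAM3	II.2	0	0	2	1
FAM3	III.4	0	0	1	1
FAM3	III.5	II.1	II.2	2	2
FAM3	III.6	II.1	II.2	1	2
FAM3	III.8	II.1	II.2	2	1
FAM3	III.9	0	0	2	1
FAM3	IV.7	III.4	III.5	2	2
FAM3	IV.8	III.4	III.5	1	2
FAM3	IV.9	III.4	III.5	2	1
FAM3	IV.10	III.6	III.9	1	2
FAM3	IV.11	III.6	III.9	2	1
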