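FAM2	I.1	0	0	1	2
FAM2	I.2	0	0	2	1
FAM2	II.1	I.1	I.2	1	2
FAM2	II.2	0	0	2	1
FAM2	II.3	I.1	I.2	2	2
FAM2	II.4	0	0	1	1
FAM2	III.7	0	0	1	1
FAM2	III.8	II.1	II.2	2	2
FAM2	III.9	II.1	II.2	1	1
FAM2	III.10	II.1	II.2	1	2
FAM2	III.11	II.4	II.3	1	2
FAM2	III.12	II.4	II.3	2	1
FAM2	III.13	II.4	II.3	2	2
FAM2	IV.11	III.7	III.8	1	2
FAM2	IV.12	III.7	III.8	2	2
FAM2	IV.13	III.7	III.8	2	1
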