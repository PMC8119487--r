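individual_id,genotype,variant_id,proband,age_years
I.1,untyped,c.1461C>G,0,90
I.2,untyped,c.1461C>G,0,88
II.1,het,c.1461C>G,0,66
II.2,ref,c.1461C>G,0,64
III.4,ref,c.1461C>G,0,44
III.5,het,c.1461C>G,0,42
III.6,het,c.1461C>G,0,40
III.8,ref,c.1461C>G,0,37
III.9,ref,c.1461C>G,0,41
IV.7,het,c.1461C>G,1,24
IV.8,het,c.1461C>G,0,21
IV.9,ref,c.1461C>G,0,18
IV.10,het,c.1461C>G,0,19
IV.11,ref,c.1461C>G,0,17
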