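individual_id,genotype,variant_id,proband,age_years
I.1,untyped,c.1460A>T,0,96
I.2,untyped,c.1460A>T,0,94
II.1,het,c.1460A>T,0,75
II.2,ref,c.1460A>T,0,73
II.3,het,c.1460A>T,0,71
II.4,ref,c.1460A>T,0,72
III.1,het,c.1460A>T,0,62
III.2,ref,c.1460A>T,0,60
III.6,het,c.1460A>T,0,58
III.3,het,c.1460A>T,0,57
III.4,ref,c.1460A>T,0,55
III.5,ref,c.1460A>T,0,63
IV.6,het,c.1460A>T,1,39
IV.7,het,c.1460A>T,0,36
IV.8,ref,c.1460A>T,0,30
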