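individual_id,genotype,variant_id,proband,age_years
I.1,untyped,c.533C>T,0,92
I.2,untyped,c.533C>T,0,90
II.1,het,c.533C>T,0,68
II.2,ref,c.533C>T,0,66
II.3,het,c.533C>T,0,64
II.4,ref,c.533C>T,0,65
III.1,het,c.533C>T,0,45
III.2,het,c.533C>T,0,43
III.3,ref,c.533C>T,0,40
III.4,het,c.533C>T,0,41
III.5,ref,c.533C>T,0,38
III.6,ref,c.533C>T,0,44
IV.1,het,c.533C>T,1,29
IV.2,het,c.533C>T,0,26
IV.3,ref,c.533C>T,0,22
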