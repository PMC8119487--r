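individual_id,genotype,variant_id,proband,age_years
I.1,untyped,c.553G>A,0,95
I.2,untyped,c.553G>A,0,93
II.1,het,c.553G>A,0,72
II.2,ref,c.553G>A,0,70
II.3,het,c.553G>A,0,69
II.4,ref,c.553G>A,0,71
III.7,ref,c.553G>A,0,48
III.8,het,c.553G>A,0,47
III.9,ref,c.553G>A,0,44
III.10,untyped,c.553G>A,0,46
III.11,het,c.553G>A,0,42
III.12,ref,c.553G>A,0,40
III.13,het,c.553G>A,0,45
IV.11,het,c.553G>A,0,21
IV.12,het,c.553G>A,1,39
IV.13,ref,c.553G>A,0,18
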