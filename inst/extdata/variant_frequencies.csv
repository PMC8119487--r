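variant_id,protein,family,gnomAD,UK10K,EVS
c.533C>T,p.Ser178Leu,FAM1,8e-06,0,0
c.553G>A,p.Asp185Asn,FAM2,0,0,0
c.1461C>G,p.His487Gln,FAM3,0,0,0
c.1460A>T,p.His487Leu,FAM4,0,0,0
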