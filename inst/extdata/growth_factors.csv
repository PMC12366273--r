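name,supplemented_conc,molecular_weight,diffusivity,half_life,ec50,media_group
FGF-alpha,5,15800,100,4320,0.3,stromal
EGF,5,6400,21,25200,0.1,stromal+vascular
FGF-beta,5,17100,92,90000,0.1,stromal+vascular
IGF-1,15,7600,159,1440,5,vascular
VEGF,5,38200,200,3600,1.7,vascular
DEX,392,392,10.8,16200,1.9,adipogenic
Insulin,1000,5808,200,108000,33.7,adipogenic
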