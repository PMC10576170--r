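((((Panthera_leo:0.21,Panthera_onca:0.18):0.35,(Lynx_rufus:0.27,Puma_concolor:0.3):0.12):0.4,((Canis_lupus:0.45,Vulpes_vulpes:0.5):0.2,((Ursus_arctos:0.6,Lutra_lutra:0.55):0.1,Mustela_nivalis:0.62):0.05):0.15):0.3,Orthriophis_taeniurus:1.4);
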