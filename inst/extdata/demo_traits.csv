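species,mass_kg
Felis_leo,190
Panthera_onca,96
Felis_rufus,9.6
Puma_concolor,62
Canis_lycaon,40
Vulpes_vulpes,6.2
Ursus_arctus,217
Mustela_vulgaris,0.08
Lutra_lutra,8.8
Elaphe_taeniura,1.4
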