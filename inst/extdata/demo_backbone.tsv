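accepted_name	synonym	status
Panthera leo	Felis leo	heterotypic
Panthera onca	Felis onca	heterotypic
Orthriophis taeniurus	Elaphe taeniura	heterotypic
Lynx rufus	Felis rufus	heterotypic
Puma concolor	Felis concolor	heterotypic
Canis lupus	Canis lycaon	homotypic
Vulpes vulpes		
Ursus arctos	Ursus arctus	orthographic
Mustela nivalis	Mustela vulgaris	heterotypic
Lutra lutra	Mustela lutra	heterotypic
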