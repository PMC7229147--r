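Struthionidae	0
Rheidae	0
Casuariidae	0
Apterygidae	0
Tinamidae	0
Megapodiidae	0
Cracidae	0
Numididae	0
Odontophoridae	0
Phasianidae	0
Anhimidae	0
Anseranatidae	2
Anatidae	1
Caprimulgidae	0
Steatornithidae	0
Nyctibiidae	0
Podargidae	0
Aegothelidae	0
Apodidae	0
Trochilidae	0
Columbidae	0
Pteroclidae	0
Mesitornithidae	0
Cuculidae	0
Otididae	0
Musophagidae	0
Psophiidae	0
Aramidae	0
Gruidae	0
Sarothruridae	0
Heliornithidae	4
Rallidae_other	0
Fulica	4
Phoenicopteridae	1
Podicipedidae	4
Burhinidae	2
Chionidae	2
Pluvianellidae	?
Haematopodidae	2
Ibidorhynchidae	2
Recurvirostridae	2
Charadriidae	2
Scolopacidae_other	0
Tringa	0
Phalaropus	4
Jacanidae	0
Rostratulidae	0
Thinocoridae	0
Pedionomidae	2
Turnicidae	0
Dromadidae	1
Glareolidae_other	1
Cursorius	2
Stercorariidae	1
Alcidae	1
Laridae	1
Eurypygidae	0
Rhynochetidae	0
Phaethontidae	3
Gaviidae	1
Spheniscidae	1
Diomedeidae	1
Hydrobatidae	1
Procellariidae	1
Ciconiidae	0
Fregatidae	3
Sulidae	3
Anhingidae	3
Phalacrocoracidae	3
Ardeidae	0
Threskiornithidae	0
Scopidae	0
Balaenicipitidae	0
Pelecanidae	3
Opisthocomidae	0
Cathartidae	0
Sagittariidae	0
Pandionidae	0
Accipitridae	0
Tytonidae	0
Strigidae	0
Coliidae	0
Leptosomidae	0
Trogonidae	0
Bucerotidae	0
Upupidae	0
Phoeniculidae	0
Meropidae	0
Coraciidae	0
Momotidae	0
Alcedinidae	0
Galbulidae	0
Ramphastidae	0
Indicatoridae	0
Picidae	0
Cariamidae	0
Falconidae	0
Psittacidae	0
Acanthisittidae	0
Tyrannidae	0
Menuridae	0
Corvidae	0
Passeridae	0
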