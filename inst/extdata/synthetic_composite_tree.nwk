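((Struthionidae,(Rheidae,((Casuariidae,Apterygidae),Tinamidae))),(((Megapodiidae,(Cracidae,(Numididae,(Odontophoridae,Phasianidae)))),(Anhimidae,(Anseranatidae,Anatidae))),((Caprimulgidae,(Steatornithidae,(Nyctibiidae,(Podargidae,(Aegothelidae,(Apodidae,Trochilidae)))))),(((Columbidae,(Pteroclidae,Mesitornithidae)),(Cuculidae,(Otididae,Musophagidae))),(((Psophiidae,(Aramidae,Gruidae)),((Sarothruridae,Heliornithidae),(Rallidae_other,Fulica))),((((Phoenicopteridae,Podicipedidae),((Burhinidae,((Chionidae,Pluvianellidae),(Haematopodidae,(Ibidorhynchidae,(Recurvirostridae,Charadriidae))))),(((Scolopacidae_other,(Tringa,Phalaropus)),(Jacanidae,(Rostratulidae,(Thinocoridae,Pedionomidae)))),(Turnicidae,((Dromadidae,(Glareolidae_other,Cursorius)),(Stercorariidae,(Alcidae,Laridae))))))),(((Eurypygidae,Rhynochetidae),Phaethontidae),(Gaviidae,((Spheniscidae,(Diomedeidae,(Hydrobatidae,Procellariidae))),(Ciconiidae,((Fregatidae,(Sulidae,(Anhingidae,Phalacrocoracidae))),(Ardeidae,(Threskiornithidae,(Scopidae,(Balaenicipitidae,Pelecanidae)))))))))),(Opisthocomidae,((Cathartidae,(Sagittariidae,(Pandionidae,Accipitridae))),((Tytonidae,Strigidae),((Coliidae,(Leptosomidae,(Trogonidae,((Bucerotidae,(Upupidae,Phoeniculidae)),((Meropidae,(Coraciidae,(Momotidae,Alcedinidae))),(Galbulidae,(Ramphastidae,(Indicatoridae,Picidae)))))))),(Cariamidae,(Falconidae,(Psittacidae,(Acanthisittidae,(Tyrannidae,(Menuridae,(Corvidae,Passeridae)))))))))))))))));
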