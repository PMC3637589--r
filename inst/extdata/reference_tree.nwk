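((Struthio_camelus,(Casuarius_casuarius,Dromaius_novaehollandiae))Palaeognathae,(((Lagopus_muta,Lagopus_lagopus),(Branta_bernicla,(Cairina_moschata,Mergus_merganser)))Galloanserae,((((Phaethon_rubricauda,Phaethon_lepturus),Podiceps_cristatus),(Mesitornis_unicolor,((Syrrhaptes_paradoxus,Pterocles_bicinctus)Pteroclidiformes,Ptilinopus_magnificus)),(Rhynochetos_jubatus,Eurypygia_helias))Metaves,((Pterodroma_macroptera,(Plegadis_falcinellus,Platalea_ajaja)),((Actitis_macularius,(Larus_argentatus,(Rynchops_niger,(Sterna_hirundo,(Anous_stolidus,Gygis_alba)))))Charadriiformes,((Cathartes_aura,(Aviceda_subcristata,Ictinia_mississippiensis)),((Harpactes_erythrocephalus,((Megalaima_virens,(Ramphastos_tucanus,Picus_viridis)),((Momotus_momota,(Baryphthengus_ruficapillus,Eumomota_superciliosa))Momotidae,Merops_apiaster))),(Opisthocomus_hoazin,(Tauraco_porphyreolophus,(((Cacatua_alba,Nymphicus_hollandicus),(Aratinga_aurea,(Pyrrhura_frontalis,Forpus_xanthopterygius)))Psittaciformes,(Acanthisitta_chloris,((Manacus_manacus,Tyrannus_melancholicus),(Malurus_cyaneus,Taeniopygia_guttata,Cyanistes_caeruleus,Sturnus_vulgaris,(Menura_novaehollandiae,(Climacteris_picumnus,((Pardalotus_punctatus,Acanthiza_pusilla),(Meliphaga_lewinii,((Sericornis_frontalis,Gerygone_igata),(Philemon_corniculatus,Petroica_boodang)))))),(Corvus_corone,(Lanius_collurio,((Pycnonotus_jocosus,Hirundo_rustica)Passerida_M86,(Bombycilla_garrulus,Turdus_merula)))),(Ptilonorhynchus_violaceus,Colluricincla_harmonica,(Erithacus_rubecula,Parus_major)))Oscines))Passeriformes)))))Landbirds))Coronaves)Neoaves)Neognathae);
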