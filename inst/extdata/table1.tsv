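# Survey of SWS1 tuning-site windows (amino-acid sites 84-94, bovine
# rhodopsin numbering) from genomic sequencing of 40 bird species across
# 21 orders. published_type is the literal printed type call ("US" for the
# southern cassowary is preserved verbatim; curated_type carries the
# curated phenotype interpretation, with palaeognaths VS by MSP priority).
# Multiple accessions per species are semicolon-separated.
order	family	species	common_name	window	published_type	curated_type	clade	accessions
Struthioniformes	Struthionidae	Struthio camelus	Common ostrich	FIFCVFCVFMV	VS	VS	Palaeognathae	HF565322
Casuariiformes	Casuariidae	Casuarius casuarius	Southern cassowary	FIFCVLCVFMV	US	VS	Palaeognathae	HF565323
Casuariiformes	Dromaiidae	Dromaius novaehollandiae	Emu	FIFCVLCVFMV	VS	VS	Palaeognathae	HF565324;HF565325
Galliformes	Phasianidae	Lagopus muta	Rock ptarmigan	FISCILSVFVV	VS	VS	Neognathae	HF565326;HF565327
Galliformes	Phasianidae	Lagopus lagopus	Willow ptarmigan	FISCILSVFVV	VS	VS	Neognathae	HF565328
Anseriformes	Anatidae	Branta bernicla	Brant goose	FISCIFSVFIV	VS	VS	Neognathae	HF565329
Anseriformes	Anatidae	Cairina moschata	Muscovy duck	FVSCXFSVFIV	VS	VS	Neognathae	HF565330
Anseriformes	Anatidae	Mergus merganser	Goosander	FISCIFSVFIV	VS	VS	Neognathae	HF565331
Procellariiformes	Procellariidae	Pterodroma macroptera	Great-winged petrel	FISCIFSVFTV	VS	VS	Neognathae	HF565332
Podicipediformes	Podicipedidae	Podiceps cristatus	Great crested grebe	FICCIFSVFTV	VS	VS	Neognathae	HF565333
Phaethontiformes	Phaethontidae	Phaethon rubricauda	Red-tailed tropicbird	FMACIFSVFTV	VS	VS	Neognathae	HM212420;HM212423;HF565334
Phaethontiformes	Phaethontidae	Phaethon lepturus fulvus	White-tailed tropicbird	FMACIFSVFTV	VS	VS	Neognathae	HF565335
Pelecaniformes	Threskiornithidae	Plegadis falcinellus	Glossy ibis	FISCIFSVFTV	VS	VS	Neognathae	HF565336
Pelecaniformes	Threskiornithidae	Platalea ajaja	Roseate spoonbill	FISCIFSVFTV	VS	VS	Neognathae	HF565337
Accipitriformes	Cathartidae	Cathartes aura ruficollis	Turkey vulture	FISCIFSVFTV	VS	VS	Neognathae	HF565338
Accipitriformes	Accipitridae	Aviceda subcristata	Pacific baza	FICCIFSVFIV	VS	VS	Neognathae	HF565339
Accipitriformes	Accipitridae	Ictinia mississippiensis	Mississippi kite	FICCIFSVFTV	VS	VS	Neognathae	HF565340
Mesitornithiformes	Mesitornithidae	Mesitornis unicolor	Brown mesite	FLCCIFSVFTV	VS	VS	Neognathae	HF565341
Eurypygiformes	Rhynochetidae	Rhynochetos jubatus	Kagu	FISCVFSVFTV	VS	VS	Neognathae	HF565342
Eurypygiformes	Eurypygidae	Eurypygia helias	Sunbittern	FISCIFSVFTV	VS	VS	Neognathae	HF565343
Charadriiformes	Scolopacidae	Actitis macularius	Spotted sandpiper	FIACIFSVFTV	VS	VS	Neognathae	AY960714
Pteroclidiformes	Pteroclididae	Syrrhaptes paradoxus	Pallas's sandgrouse	FIFCTFSVFTV	UVS	UVS	Neognathae	HF565344;HF565345
Pteroclidiformes	Pteroclididae	Pterocles bicinctus	Double-banded sandgrouse	FIFCSFSVFTV	UVS	UVS	Neognathae	HF565346
Columbiformes	Columbidae	Ptilinopus magnificus	Wompoo fruit dove	FISCIFSVFTV	VS	VS	Neognathae	HF565347
Psittaciformes	Cacatuidae	Cacatua alba	White cockatoo	FLACIFCIFTV	UVS	UVS	Neognathae	HF565348
Psittaciformes	Cacatuidae	Nymphicus hollandicus	Cockatiel	FLACIFCIFTV	UVS	UVS	Neognathae	HF565349
Psittaciformes	Psittacidae	Aratinga aurea	Peach-fronted parakeet	FLACIFCIFTV	UVS	UVS	Neognathae	HF565350
Psittaciformes	Psittacidae	Pyrrhura frontalis	Maroon-bellied parakeet	FLACIFCIFTV	UVS	UVS	Neognathae	HF565351
Psittaciformes	Psittacidae	Forpus xanthopterygius	Blue-winged parrotlet	FLACIFCIFTV	UVS	UVS	Neognathae	HF565352
Opisthocomiformes	Opisthocomidae	Opisthocomus hoazin	Hoatzin	FICCIFSVFTV	VS	VS	Neognathae	HF565353
Musophagiformes	Musophagidae	Tauraco porphyreolophus	Purple-crested turaco	FISCIFSVFTV	VS	VS	Neognathae	HF565354
Trogoniformes	Trogonidae	Harpactes erythrocephalus	Red-headed trogon	FIFCVFSVFTV	UVS	UVS	Neognathae	HF565355
Coraciiformes	Momotidae	Momotus momota	Amazonian motmot	FIFCSFSVFTV	UVS	UVS	Neognathae	HF565356
Coraciiformes	Momotidae	Baryphthengus ruficapillus	Rufous-capped motmot	FIFCSFSVFTV	UVS	UVS	Neognathae	HF565357
Coraciiformes	Momotidae	Eumomota superciliosa	Turquoise-browed motmot	FIFCSFSVFTV	UVS	UVS	Neognathae	HF565358
Coraciiformes	Meropidae	Merops apiaster	European bee-eater	FVSCIFSVFTV	VS	VS	Neognathae	HF565359
Piciformes	Megalaimidae	Megalaima virens	Great barbet	FISCIFSVFTV	VS	VS	Neognathae	HF565360
Piciformes	Ramphastidae	Ramphastos tucanus	White-throated toucan	FISCIFSVFTV	VS	VS	Neognathae	HF565361
Piciformes	Picidae	Picus viridis	European green woodpecker	FLSCIFSVFTV	VS	VS	Neognathae	HF565362
Passeriformes	Pipridae	Manacus manacus	White-bearded manakin	FMCCIFSVFTV	VS	VS	Neognathae	HF565363;AY227182
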