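# Tip states for the packaged reference tree. Characters:
#   phenotype: binary UVS/VS after overrides (palaeognaths VS by MSP priority)
#   route:     phenotype with the causal route resolved {VS, UVS_C90, UVS_F86}
#   site86/site90: residue characters (genotype; palaeognaths F86/C90)
# source: this_study = from the packaged 40-species survey;
#         prior = state taken from earlier studies; representatives of the
#         expanded Charadriiformes/Passeriformes clades are stylized (see
#         the package vignette).
tip	phenotype	route	site86	site90	source
Struthio_camelus	VS	VS	F	C	this_study
Casuarius_casuarius	VS	VS	F	C	this_study
Dromaius_novaehollandiae	VS	VS	F	C	this_study
Lagopus_muta	VS	VS	S	S	this_study
Lagopus_lagopus	VS	VS	S	S	this_study
Branta_bernicla	VS	VS	S	S	this_study
Cairina_moschata	VS	VS	S	S	this_study
Mergus_merganser	VS	VS	S	S	this_study
Phaethon_rubricauda	VS	VS	A	S	this_study
Phaethon_lepturus	VS	VS	A	S	this_study
Podiceps_cristatus	VS	VS	C	S	this_study
Mesitornis_unicolor	VS	VS	C	S	this_study
Syrrhaptes_paradoxus	UVS	UVS_F86	F	S	this_study
Pterocles_bicinctus	UVS	UVS_F86	F	S	this_study
Ptilinopus_magnificus	VS	VS	S	S	this_study
Rhynochetos_jubatus	VS	VS	S	S	this_study
Eurypygia_helias	VS	VS	S	S	this_study
Pterodroma_macroptera	VS	VS	S	S	this_study
Plegadis_falcinellus	VS	VS	S	S	this_study
Platalea_ajaja	VS	VS	S	S	this_study
Actitis_macularius	VS	VS	A	S	this_study
Larus_argentatus	UVS	UVS_C90	I	C	prior
Rynchops_niger	UVS	UVS_C90	A	C	prior
Sterna_hirundo	VS	VS	T	S	prior
Anous_stolidus	UVS	UVS_C90	A	C	prior
Gygis_alba	UVS	UVS_C90	A	C	prior
Cathartes_aura	VS	VS	S	S	this_study
Aviceda_subcristata	VS	VS	C	S	this_study
Ictinia_mississippiensis	VS	VS	C	S	this_study
Harpactes_erythrocephalus	UVS	UVS_F86	F	S	this_study
Megalaima_virens	VS	VS	S	S	this_study
Ramphastos_tucanus	VS	VS	S	S	this_study
Picus_viridis	VS	VS	S	S	this_study
Momotus_momota	UVS	UVS_F86	F	S	this_study
Baryphthengus_ruficapillus	UVS	UVS_F86	F	S	this_study
Eumomota_superciliosa	UVS	UVS_F86	F	S	this_study
Merops_apiaster	VS	VS	S	S	this_study
Opisthocomus_hoazin	VS	VS	C	S	this_study
Tauraco_porphyreolophus	VS	VS	S	S	this_study
Cacatua_alba	UVS	UVS_C90	A	C	this_study
Nymphicus_hollandicus	UVS	UVS_C90	A	C	this_study
Aratinga_aurea	UVS	UVS_C90	A	C	this_study
Pyrrhura_frontalis	UVS	UVS_C90	A	C	this_study
Forpus_xanthopterygius	UVS	UVS_C90	A	C	this_study
Acanthisitta_chloris	UVS	UVS_C90	S	C	prior
Manacus_manacus	VS	VS	C	S	this_study
Tyrannus_melancholicus	VS	VS	S	S	prior
Malurus_cyaneus	UVS	UVS_C90	S	C	prior
Taeniopygia_guttata	UVS	UVS_C90	C	C	prior
Cyanistes_caeruleus	UVS	UVS_C90	S	C	prior
Sturnus_vulgaris	UVS	UVS_C90	S	C	prior
Menura_novaehollandiae	VS	VS	S	S	prior
Climacteris_picumnus	VS	VS	S	S	prior
Pardalotus_punctatus	UVS	UVS_C90	S	C	prior
Acanthiza_pusilla	UVS	UVS_C90	S	C	prior
Meliphaga_lewinii	VS	VS	S	S	prior
Sericornis_frontalis	UVS	UVS_C90	S	C	prior
Gerygone_igata	UVS	UVS_C90	S	C	prior
Philemon_corniculatus	VS	VS	S	S	prior
Petroica_boodang	VS	VS	S	S	prior
Corvus_corone	VS	VS	S	S	prior
Lanius_collurio	VS	VS	S	S	prior
Pycnonotus_jocosus	UVS	UVS_C90	M	C	prior
Hirundo_rustica	UVS	UVS_C90	M	C	prior
Bombycilla_garrulus	VS	VS	S	S	prior
Turdus_merula	VS	VS	S	S	prior
Ptilonorhynchus_violaceus	VS	VS	S	S	prior
Colluricincla_harmonica	VS	VS	S	S	prior
Erithacus_rubecula	UVS	UVS_C90	S	C	prior
Parus_major	UVS	UVS_C90	S	C	prior
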