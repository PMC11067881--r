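clade	species	role
Metazoa	Hydractinia_symbiolongicarpus,Hydractinia_echinata,Clytia_hemisphaerica,Hydra_vulgaris,Hydra_viridissima,Podocoryna_carnea,Turritopsis_dohrnii,Craspedacusta_sowerbii,Aurelia_aurita_pacific,Aurelia_aurita_atlantic,Morbakka_virulenta,Nematostella_vectensis,Exaiptasia_diaphana,Acropora_millepora,Dendronephthya_gigantea,Homo_sapiens,Drosophila_melanogaster,Caenorhabditis_elegans,Branchiostoma_floridae	metazoa
Cnidaria	Hydractinia_symbiolongicarpus,Hydractinia_echinata,Clytia_hemisphaerica,Hydra_vulgaris,Hydra_viridissima,Podocoryna_carnea,Turritopsis_dohrnii,Craspedacusta_sowerbii,Aurelia_aurita_pacific,Aurelia_aurita_atlantic,Morbakka_virulenta,Nematostella_vectensis,Exaiptasia_diaphana,Acropora_millepora,Dendronephthya_gigantea	focal_phylum
Medusozoa	Hydractinia_symbiolongicarpus,Hydractinia_echinata,Clytia_hemisphaerica,Hydra_vulgaris,Hydra_viridissima,Podocoryna_carnea,Turritopsis_dohrnii,Craspedacusta_sowerbii,Aurelia_aurita_pacific,Aurelia_aurita_atlantic,Morbakka_virulenta	
Hydrozoa	Hydractinia_symbiolongicarpus,Hydractinia_echinata,Clytia_hemisphaerica,Hydra_vulgaris,Hydra_viridissima,Podocoryna_carnea,Turritopsis_dohrnii,Craspedacusta_sowerbii	
Anthozoa	Nematostella_vectensis,Exaiptasia_diaphana,Acropora_millepora,Dendronephthya_gigantea	
Bilateria	Homo_sapiens,Drosophila_melanogaster,Caenorhabditis_elegans,Branchiostoma_floridae	
Hydractinia_Clytia	Hydractinia_symbiolongicarpus,Hydractinia_echinata,Clytia_hemisphaerica,Podocoryna_carnea	
Outgroups	Monosiga_brevicollis,Capsaspora_owczarzaki,Saccharomyces_cerevisiae	outgroup
Hydractinia	Hydractinia_symbiolongicarpus,Hydractinia_echinata	
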