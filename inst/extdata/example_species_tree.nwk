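(((((((((Hydractinia_symbiolongicarpus,Hydractinia_echinata)Hydractinia_mrca,Podocoryna_carnea)HydrPod,Clytia_hemisphaerica)HydrCly,(Turritopsis_dohrnii,Craspedacusta_sowerbii)OtherHydro)CoreHydro,(Hydra_vulgaris,Hydra_viridissima)Hydra)Hydrozoa_mrca,((Aurelia_aurita_pacific,Aurelia_aurita_atlantic)Aurelia,Morbakka_virulenta)Acraspeda)Medusozoa_mrca,((Nematostella_vectensis,Exaiptasia_diaphana)Actiniaria,(Acropora_millepora,Dendronephthya_gigantea)OtherAntho)Anthozoa_mrca)Cnidaria_mrca,((Homo_sapiens,Branchiostoma_floridae)Chordata,(Drosophila_melanogaster,Caenorhabditis_elegans)Ecdysozoa)Bilateria_mrca)Metazoa_mrca,(Monosiga_brevicollis,(Capsaspora_owczarzaki,Saccharomyces_cerevisiae)Opisthokonta_out)Outgroup_mrca)Root;
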