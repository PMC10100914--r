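taxon_id	domain	marker	lineage
asv_bact1	bacteria	16S	Bacteria;Desulfobacterota;SEEP-SRB1
asv_bact2	bacteria	16S	Bacteria;Campylobacterota;Sulfurovum
asv_arch1	archaea	16S	Archaea;Halobacterota;ANME-1b
asv_fun1	fungus	18S	Fungi;Ascomycota;Fusarium
asv_fun2	fungus	18S	Fungi;Basidiomycota;Malassezia
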