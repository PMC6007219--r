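# synthetic test lexicon: taxonomy IDs printed in the source material only;
# padding entries use clearly synthetic IDs >= 10^7
9606	Homo sapiens	scientific
9606	human	common
1280	Staphylococcus aureus	scientific
1280	MRSA	abbreviation
367830	Staphylococcus aureus subsp. aureus USA300	scientific
367830	USA300	strain
7955	Danio rerio	scientific
7955	zebrafish	common
10090	Mus musculus	scientific
10090	mouse	common
10090	mice	common
10090	C57BL/6	strain
6239	Caenorhabditis elegans	scientific
6239	C. elegans	abbreviation
9031	Gallus gallus	scientific
9031	chicken	common
7227	Drosophila melanogaster	scientific
90371	Salmonella enterica subsp. enterica serovar Typhimurium	scientific
90371	Salmonella typhimurium	general
5691	Trypanosoma brucei	scientific
11646	Lentivirus	scientific
11646	LV	abbreviation
3701	Arabidopsis	scientific
3701	Col-0	strain
3702	Arabidopsis thaliana	scientific
3702	Arabidopsis	general
3915	AR3915 reference line	general
10000001	Synthorg alphaensis	scientific
10000001	synthorg	common
10000002	Synthorg betagensis	scientific
10000002	synthorg	common
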