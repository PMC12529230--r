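peak_id	length_bp	summit_region	fold_enrichment	covered_genes
472q	1551	ORF	4.6	msed_2065:Iron-dependent repressor|msed_2066:Uncharacterized membrane-associated protein|msed_2067:Probable membrane transporter protein
463d	1864	ORF	4.6	msed_2031:Hypothetical protein|msed_2032:Cytochrome c oxidase, subunit I
233f	928	Intergenic*	4.4	msed_0969:Holliday junction resolvase|msed_0970:Putative signal-transduction protein with CBS domains|msed_0972:Major facilitator superfamily
89d	1692	Intergenic*	4.2	msed_0413:Hypothetical protein|msed_0414:Hypothetical protein|msed_0415:NADH/flavin oxidoreductase/NADH oxidase
263b	816	Intergenic	4.2	msed_1082:Hypothetical protein|msed_1083:Hypothetical protein
178d	1239	Intergenic*	4.1	msed_0775:FAD-dependent oxidoreductase|msed_0776:Thioredoxin|msed_0777:Hypothetical protein
198c	1390	Intergenic*	4.0	msed_0850:YncE family protein|msed_0851:Peptidase S53 family protein
84	1310	Intergenic*	4.0	msed_0396:Thiolase|msed_0397:3-hydroxybutyryl-CoA epimerase|msed_0398:Alcohol dehydrogenase GroES domain protein
221a	1110	Intergenic*	3.8	msed_0933:Hydrogenase expression/formation protein HypE|msed_0934:Hypothetical protein
344a	1492	Intergenic*	3.8	msed_1382:Binding-protein-dependent transport system membrane component|msed_1383:von Willebrand factor, type A
122b	841	Intergenic*	3.6	msed_0504:Cytochrome b558/566 subunit A, CbsA|msed_0505:Plasma-membrane proton-efflux P-type ATPase
45d	1560	Intergenic*	3.6	msed_0257:tRNA(Met) cytidine acetyltransferase, TmcA|msed_0258:Major facilitator superfamily1
135e	1032	ORF*	3.6	msed_0558:Sulfide dehydrogenase (flavocytochrome), flavoprotein subunit|msed_0559:GTP:adenosylcobinamide-phosphate guanylyltransferase-like protein
366a	1877	ORF*	3.6	msed_1484:Peptidase M20|msed_1485:Hypothetical protein|msed_1486:Primase X domain-containing protein|msed_1487:PP-loop domain protein
264	637	Intergenic*	3.5	msed_1091:Dihydrolipoamide dehydrogenase|msed_1092:Pirin domain protein
34c	842	ORF*	3.5	msed_0183:Glycosyl transferase, family 2|msed_0184:Phosphomethylpyrimidine kinase
168a	1836	ORF	3.5	msed_0747:Ribosomal RNA small subunit methyltransferase, Nep1|msed_0748:Hypothetical protein|msed_0749:Peptide chain release factor subunit 1, prf1
68b	1304	Intergenic*	3.5	msed_0353:FAD-dependent pyridine nucleotide-disulfide oxidoreductase|msed_0354:SirA family protein|msed_0355:DNA helicase
268a	1545	Intergenic	3.4	msed_1116:Fumarase alpha subunit|msed_1117:Major facilitator superfamily
148d	1280	Intergenic*	3.3	msed_0631:Dihydropteroate synthase-related protein|msed_0632:Thioredoxin reductase (NADPH)
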