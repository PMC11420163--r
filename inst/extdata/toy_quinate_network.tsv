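# flat metabolic network
# MANIFEST compounds=11 reactions=9 pathways=2
COMPOUND	quinate	quinate	carbohydrate	0	quinic acid
COMPOUND	dhq	3-dehydroquinate	carbohydrate	0	
COMPOUND	dhs	3-dehydroshikimate	carbohydrate	0	
COMPOUND	pca	protocatechuate	other	0	PCA
COMPOUND	bka	beta-ketoadipate	other	0	
COMPOUND	chorismate	chorismate	other	0	
COMPOUND	prephenate	prephenate	other	1	
COMPOUND	tyr	L-tyrosine	amino_acid	0	tyrosine|Tyr
COMPOUND	succ	succinate	other	0	
COMPOUND	fum	fumarate	other	0	
COMPOUND	mal	malate	other	0	
REACTION	rxn-quiA	quinate	dhq	quiA	0
REACTION	rxn-quiB	dhq	dhs	quiB	0
REACTION	rxn-quiC	dhs	pca	quiC	0
REACTION	rxn-pcaGH	pca	bka	pcaG,pcaH	0
REACTION	rxn-aroQ	chorismate	prephenate	aroQ	1
REACTION	rxn-tyrA	prephenate	tyr	tyrA	0
REACTION	rxn-sdh	succ	fum	sdhA,sdhB	0
REACTION	rxn-fumC	fum	mal	fumC	1
REACTION	rxn-shunt	quinate	pca	quiX	0
PATHWAY	pwy-quinate-deg	quinate degradation	degradation/aromatic_compound	rxn-quiA,rxn-quiB,rxn-quiC,rxn-pcaGH
PATHWAY	pwy-tyr-syn	tyrosine biosynthesis	biosynthesis/amino_acid	rxn-aroQ,rxn-tyrA
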