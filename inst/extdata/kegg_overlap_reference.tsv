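pathway	category	protein	gse1297	gse5281
Cytokine-cytokine receptor interaction	Signaling Molecules and Interaction	enriched		significant
Neuroactive ligand-receptor migration	Signaling Molecules and Interaction	significant	significant	significant
ECM-receptor interaction	Signaling Molecules and Interaction		enriched	significant
Antigen processing and presentation	Immune System		significant	significant
Hematopoietic cell lineage	Immune System	enriched	significant	significant
Leukocyte transendothelial migration	Immune System	significant		significant
MAPK signaling pathway	Signal Transduction	enriched	significant	significant
Focal adhesion	Cell Communication	significant	significant	significant
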