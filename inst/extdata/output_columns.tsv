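file	column	description
chains.tsv	tree_id	tree identifier (<cell type>.<root node name>)
chains.tsv	cell_type	cell type of the tree
chains.tsv	gene_id	gene of the root promoter
chains.tsv	e1	level-1 enhancer node name
chains.tsv	e2	level-2 enhancer node name (empty for E1-only records)
chains.tsv	d_e1	unsigned bp from the E1 midpoint to the root TSS
chains.tsv	d_e2	unsigned bp from the E2 midpoint to the root TSS
chains.tsv	pet_l1	PET count of the promoter-E1 (L1) edge
chains.tsv	pet_l3	PET count of the E1-E2 (L3) edge
skipping.tsv	e1	assessed level-1 enhancer node
skipping.tsv	looped_gene	gene of the tree root the enhancer loops to
skipping.tsv	nearest_gene	closest TSS 5 kb-1 Mb from the enhancer midpoint
skipping.tsv	skipped	TRUE when the looped gene differs from the nearest gene
skipping.tsv	skipped_biotype	coding/noncoding status of the skipped gene
skipping.tsv	orientation	InsideLoop (same side) or OutsideLoop (opposite sides)
skipping.tsv	ess_winner	which gene has the higher expression specificity (looped/skipped/tie/unknown)
skipping.tsv	abundance_winner	which gene has the higher transcript abundance
effect_sizes.tsv	node_name	enhancer node scored by in silico removal
effect_sizes.tsv	effect_size	mean over repetitions of the summed absolute accuracy deviation D(e)
effect_sizes.tsv	rank	rank within its tree (1 = largest effect size)
snp_links.tsv	link_id	unique (SNP, node, tree) identifier
snp_links.tsv	gwas_p	association p-value of the SNP
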