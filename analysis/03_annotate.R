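#!/usr/bin/env Rscript

# Stage 3: associate the wild-type DMRs with the gene/TE annotation:
# location category per DMR (TE > genic > intergenic), genes within
# 500 bp of a DMR, the 5'-region flag, and the TE-proximity contrast
# between DMR-associated genes and the whole gene set.

suppressMessages(library(pollenDMR))

feats <- parse_gff("results/data/features.gff3")
dmrs <- read_dmr_table("results/dmrs_wt.tsv")

ann <- annotate_dmrs(dmrs, feats$genes, feats$tes, window = 500L)
write.table(ann, "results/dmrs_wt_annotated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat_tab <- table(context = ann$context, direction = ann$direction,
                 category = ann$category)
write.table(as.data.frame(cat_tab), "results/dmr_category_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
hy <- ann[ann$context == "CG" & ann$direction == "hypo", ]
message(sprintf("CG-hypo DMRs by category: %s",
                paste(names(table(hy$category)), table(hy$category),
                      collapse = ", ")))
message(sprintf("CG-hypo DMRs in a 5'-region: %d of %d",
                sum(hy$in_5prime), nrow(hy)))

assoc <- associate_genes(hy, feats$genes, window = 500L)
write.table(assoc, "results/dmr_gene_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
assoc_genes <- feats$genes[feats$genes$id %in% assoc$gene_id, ]
tp_assoc <- te_proximal_fraction(assoc_genes, feats$tes, 500L)$fraction
tp_all <- te_proximal_fraction(feats$genes, feats$tes, 500L)$fraction
message(sprintf(
  "TE within 500 bp: %.1f%% of DMR-associated genes (n=%d) vs %.1f%% of all genes (n=%d)",
  100 * tp_assoc, nrow(assoc_genes), 100 * tp_all, nrow(feats$genes)))
writeLines(sort(unique(assoc$gene_id)), "results/dmr_gene_list.txt")
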