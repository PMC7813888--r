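#!/usr/bin/env Rscript

# Stage 4: gene-set enrichment of the DMR-associated genes against a
# synthetic term collection built over the simulated gene universe.
# One term is deliberately constructed from TE-proximal genes — the
# class VC demethylation targets — so a real enrichment signal exists;
# the remainder are random draws. Results mirror the standard
# enrichment-table layout (count, %, Fisher p, fold enrichment) and are
# filtered at p < 0.02.

suppressMessages(library(pollenDMR))

set.seed(20260924L)
feats <- parse_gff("results/data/features.gff3")
background <- feats$genes$id
gene_list <- readLines("results/dmr_gene_list.txt")

prox <- te_proximal_fraction(feats$genes, feats$tes, 500L)$flags
term_sets <- c(
  list(te_proximal_genes = names(prox)[prox]),
  setNames(lapply(1:8, function(i)
    sample(background, sample(5:15, 1))), paste0("random_set_", 1:8)))

# write / re-read as GMT so the standard interchange path is exercised
gmt <- "results/term_sets.gmt"
writeLines(vapply(names(term_sets), function(nm)
  paste(c(nm, "synthetic term", term_sets[[nm]]), collapse = "\t"), ""),
  gmt)

res <- term_enrichment(gene_list, read_gmt(gmt), background)
write_enrichment_tsv(res, "results/enrichment_all.tsv")
strong <- filter_enrichment(res, p_max = 0.02)
write_enrichment_tsv(strong, "results/enrichment_p_lt_0.02.tsv")

message(sprintf("%d of %d terms hold at least one listed gene; %d at p < 0.02",
                nrow(res), length(term_sets), nrow(strong)))
for (i in seq_len(nrow(strong)))
  message(sprintf("  %s: count %d (%.1f%%), p = %.3g, fold = %.2f",
                  strong$term[i], strong$count[i], strong$percent[i],
                  strong$p_value[i], strong$fold_enrichment[i]))
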