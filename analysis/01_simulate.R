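#!/usr/bin/env Rscript

# Stage 1: build the synthetic study inputs.
#
# Generates a 200-kb chromosome with TE and gene annotations, plants
# CG-demethylated (TE-hypo) and promoter-hyper truth regions, and
# simulates bisulfite methylomes for the four pools the downstream
# stages compare: wild-type VC and SC, plus a half-demethylating VC
# emulating a heterozygous demethylase-mutant father. All outputs are
# standard formats under results/data/.

suppressMessages(library(pollenDMR))

seed <- 20260924L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
cfg_mix <- simulation_config(seed = seed, mixing_fraction = 0.5)

layout <- make_genome(cfg)
truth <- plant_truth(cfg, layout)
message(sprintf("genome: %d bp, %d TEs (%.1f%% of sequence), %d genes",
                cfg$genome_length, nrow(layout$tes),
                100 * sum(layout$tes$end - layout$tes$start) /
                  cfg$genome_length, nrow(layout$genes)))
message(sprintf("planted truth: %d TE-hypo + %d promoter-hyper CG regions",
                sum(truth$kind == "TE-hypo"),
                sum(truth$kind == "promoter-hyper")))

write_genome_fasta(layout$genome, file.path(out, "genome.fa"))
write_gff(layout$genes, layout$tes, file.path(out, "features.gff3"))
write.table(truth, file.path(out, "truth_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

samples <- list(
  VC_wt = simulate_sample(truth, layout, "VC", "functional", cfg),
  SC_wt = simulate_sample(truth, layout, "SC", "functional", cfg),
  VC_het = simulate_sample(truth, layout, "VC", "functional", cfg_mix),
  SC_het = simulate_sample(truth, layout, "SC", "functional", cfg_mix))
for (nm in names(samples)) {
  path <- file.path(out, paste0(nm, ".cx_report.tsv"))
  write_cytosine_report(samples[[nm]], path, genome = layout$genome)
  message("wrote ", path, " (", nrow(samples[[nm]]), " cytosines)")
}
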